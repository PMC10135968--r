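set,receptor,interface,compound,N,modulation_mean,modulation_sd,n,c_mean,c_sd,dG_mean,dG_sd,constitutive,p_const_mean,p_const_sd,p_bg_mean,p_bg_sd
pam,alpha1beta2gamma2L,wild_type,NS-1738,2,316,123,25,0.561,0.106,-0.70,0.23,0,,,0.05,0.03
pam,beta2(V258M),b+/a-,NS-1738,2,720,140,5,0.307,0.044,-1.40,0.16,0,,,0.09,0.02
pam,beta2(T262V),b+/a-,NS-1738,2,126,12,5,0.883,0.045,-0.15,0.06,0,,,0.08,0.03
pam,beta2(F289T),b+/a-,NS-1738,2,21,14,5,2.980,1.097,1.22,0.47,1,0.25,0.06,,
pam,beta2(F289A),b+/a-,NS-1738,2,74,55,5,1.525,0.845,0.37,0.60,1,0.035,0.030,,
pam,alpha1(I227W),b+/a-,NS-1738,2,207,56,5,0.769,0.163,-0.33,0.24,0,,,0.07,0.03
pam,alpha1(L231C),b+/a-,NS-1738,2,349,133,5,0.532,0.105,-0.76,0.23,0,,,0.06,0.02
pam,alpha1(M235W),b+/a-,NS-1738,2,196,46,5,0.713,0.108,-0.41,0.17,1,0.053,0.023,,
pam,beta2(L223W),"a+/b-,g+/b-",NS-1738,2,215,26,5,0.635,0.054,-0.54,0.10,0,,,,
pam,beta2(Q224A),"a+/b-,g+/b-",NS-1738,2,389,182,6,0.492,0.118,-0.87,0.28,0,,,,
pam,beta2(M227C),"a+/b-,g+/b-",NS-1738,2,335,62,5,0.533,0.055,-0.75,0.12,0,,,,
pam,gamma2L(L275C),g+/b-,NS-1738,2,283,66,5,0.569,0.082,-0.67,0.16,0,,,,
pam,gamma2L(T277I),g+/b-,NS-1738,2,511,178,5,0.375,0.082,-1.18,0.26,1,0.08,0.05,,
pam,gamma2L(T281I),g+/b-,NS-1738,2,262,61,6,0.592,0.078,-0.63,0.16,0,,,,
pam,gamma2L(F304C),g+/b-,NS-1738,2,34,17,5,1.917,0.449,0.74,0.29,1,0.15,0.07,,
pam,alpha1(T264V),"a+/g-,a+/b-",NS-1738,2,295,63,5,0.530,0.079,-0.76,0.17,0,,,,
pam,alpha1(T266M),"a+/g-,a+/b-",NS-1738,2,151,39,5,0.189,0.107,-0.24,0.16,0,,,,
pam,alpha1(W287A),"a+/g-,a+/b-",NS-1738,2,292,81,5,0.584,0.091,-0.65,0.18,0,,,,
pam,alpha1(A290C),"a+/g-,a+/b-",NS-1738,2,262,41,5,0.596,0.042,-0.61,0.08,0,,,,
pam,alpha1(Y293F),"a+/g-,a+/b-",NS-1738,2,311,140,5,0.567,0.133,-0.70,0.29,0,,,,
pam,alpha1(Y293C),"a+/g-,a+/b-",NS-1738,2,62,14,5,1.310,0.164,0.31,0.14,0,,,,
pam,gamma2L(I242W),a+/g-,NS-1738,2,314,44,5,0.541,0.045,-0.73,0.10,0,,,,
pam,gamma2L(I242S),a+/g-,NS-1738,2,376,106,6,0.493,0.099,-0.85,0.21,0,,,,
pam,gamma2L(L246W),a+/g-,NS-1738,2,150,23,5,0.800,0.081,-0.27,0.12,1,0.07,0.04,,
pam,gamma2L(L246N),a+/g-,NS-1738,2,40,25,5,2.161,1.150,0.80,0.55,1,0.25,0.05,,
pam,alpha1beta2gamma2L,wild_type,PAM-2,2,189,36,25,0.721,0.061,-0.39,0.10,0,,,0.06,0.03
pam,beta2(V258M),b+/a-,PAM-2,2,301,87,5,0.559,0.110,-0.70,0.22,0,,,0.10,0.04
pam,beta2(T262V),b+/a-,PAM-2,2,121,9,5,0.906,0.032,-0.12,0.04,0,,,0.05,0.03
pam,beta2(F289T),b+/a-,PAM-2,2,98,29,8,1.058,0.206,0.05,0.23,1,0.23,0.06,,
pam,beta2(F289A),b+/a-,PAM-2,2,87,20,5,1.094,0.123,0.10,0.13,1,0.035,0.021,,
pam,alpha1(I227W),b+/a-,PAM-2,2,135,18,5,0.856,0.059,-0.19,0.08,0,,,0.07,0.03
pam,alpha1(L231C),b+/a-,PAM-2,2,197,19,5,0.691,0.037,-0.44,0.06,0,,,0.10,0.02
pam,alpha1(M235W),b+/a-,PAM-2,2,174,20,5,0.749,0.041,-0.34,0.06,1,0.042,0.026,,
pam,beta2(L223W),"a+/b-,g+/b-",PAM-2,2,48,10,5,1.540,0.157,0.50,0.13,0,,,0.26,0.13
pam,beta2(Q224A),"a+/b-,g+/b-",PAM-2,2,169,26,5,0.752,0.058,-0.34,0.09,0,,,,
pam,beta2(M227C),"a+/b-,g+/b-",PAM-2,2,143,18,5,0.833,0.051,-0.22,0.07,0,,,,
pam,gamma2L(L275C),g+/b-,PAM-2,2,251,21,5,0.611,0.029,-0.58,0.06,0,,,,
pam,gamma2L(T277I),g+/b-,PAM-2,2,117,6,5,0.919,0.025,-0.10,0.03,1,0.08,0.05,,
pam,gamma2L(T281I),g+/b-,PAM-2,2,255,40,5,0.687,0.051,-0.45,0.09,0,,,,
pam,gamma2L(F304C),g+/b-,PAM-2,2,40,17,5,1.791,0.428,0.66,0.28,1,0.15,0.07,,
pam,alpha1(T264V),"a+/g-,a+/b-",PAM-2,2,240,51,5,0.620,0.075,-0.57,0.14,0,,,,
pam,alpha1(T266M),"a+/g-,a+/b-",PAM-2,2,147,66,6,0.855,0.133,-0.20,0.21,0,,,,
pam,alpha1(W287A),"a+/g-,a+/b-",PAM-2,2,182,57,6,0.747,0.092,-0.35,0.16,0,,,,
pam,alpha1(A290C),"a+/g-,a+/b-",PAM-2,2,215,45,5,0.659,0.082,-0.50,0.14,0,,,,
pam,alpha1(Y293F),"a+/g-,a+/b-",PAM-2,2,184,56,5,0.735,0.095,-0.37,0.16,0,,,,
pam,alpha1(Y293C),"a+/g-,a+/b-",PAM-2,2,122,7,6,0.899,0.025,-0.13,0.03,0,,,,
pam,gamma2L(I242W),a+/g-,PAM-2,2,166,12,5,0.766,0.030,-0.31,0.05,0,,,,
pam,gamma2L(I242S),a+/g-,PAM-2,2,174,12,5,0.744,0.031,-0.35,0.05,0,,,,
pam,gamma2L(L246W),a+/g-,PAM-2,2,115,5,5,0.928,0.022,-0.09,0.03,1,0.07,0.04,,
pam,gamma2L(L246N),a+/g-,PAM-2,2,75,5,5,1.205,0.047,0.22,0.05,1,0.25,0.05,,
anesthetic,alpha1beta2gamma2L,wild_type,propofol,4,1677,1039,6,0.302,0.039,-2.84,0.33,0,,,0.07,0.04
anesthetic,gamma2L(L246N),a+/g-,propofol,4,209,49,6,0.677,0.122,-0.96,0.45,1,0.33,0.07,,
anesthetic,alpha1beta2gamma2L,wild_type,etomidate,2,1685,501,6,0.129,0.030,-2.45,0.27,0,,,0.05,0.02
anesthetic,gamma2L(L246N),a+/g-,etomidate,2,187,22,6,0.525,0.184,-0.87,0.63,1,0.33,0.07,,
anesthetic,alpha1beta2gamma2L,wild_type,3a5bP,2,715,271,15,0.303,0.069,-1.45,0.34,0,,,0.07,0.04
anesthetic,gamma2L(L246N),a+/g-,3a5bP,2,181,9,5,0.604,0.050,-0.60,0.10,1,0.29,0.06,,
steroid,alpha1beta2gamma2L,wild_type,3a5bP,2,733,183,15,0.330,0.038,-1.31,0.14,0,,,,
steroid,beta2(F289A),b+/a-,3a5bP,2,463,118,5,0.453,0.043,-0.94,0.12,1,0.025,0.019,,
steroid,alpha1(M235W),b+/a-,3a5bP,2,614,116,6,0.304,0.046,-1.42,0.19,1,0.048,0.025,,
steroid,gamma2L(T277I),g+/b-,3a5bP,2,471,262,5,0.473,0.110,-0.91,0.29,1,0.08,0.05,,
steroid,gamma2L(F304C),g+/b-,3a5bP,2,255,31,6,0.493,0.091,-0.86,0.26,1,0.15,0.07,,
steroid,beta2(L223W),"a+/b-,g+/b-",3a5bP,2,653,186,5,0.298,0.057,-1.45,0.22,1,,,,
steroid,alpha1(Y293C),"a+/g-,a+/b-",3a5bP,2,666,209,5,0.266,0.055,-1.58,0.23,0,,,,
steroid,gamma2L(L246N),a+/g-,3a5bP,2,181,9,5,0.604,0.050,-0.60,0.10,1,0.25,0.05,,
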