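nucleotide,sugar,base,pathway,phase,anomer,dg_step1,dg_step2,dg_total_printed,ddg_printed
dAMP,deoxyribose,A,ab,vacuum,alpha,2.5,-6.2,-3.7,-9.1
dAMP,deoxyribose,A,ab,vacuum,beta,2.1,-14.9,-12.8,-9.1
dGMP,deoxyribose,G,ab,vacuum,alpha,4.6,-8.8,-4.3,-18.6
dGMP,deoxyribose,G,ab,vacuum,beta,2.6,-25.4,-22.8,-18.6
dCMP,deoxyribose,C,ab,vacuum,alpha,6.5,-14.8,-8.3,1.9
dCMP,deoxyribose,C,ab,vacuum,beta,4.8,-11.3,-6.4,1.9
dTMP,deoxyribose,T,ab,vacuum,alpha,8.1,-19.7,-11.7,4.9
dTMP,deoxyribose,T,ab,vacuum,beta,6.9,-13.7,-6.7,4.9
dUMP,deoxyribose,U,ab,vacuum,alpha,7.8,-20.2,-12.3,5.2
dUMP,deoxyribose,U,ab,vacuum,beta,7.0,-14.2,-7.2,5.2
AMP,ribose,A,ab,vacuum,alpha,2.3,-6.9,-4.6,-12.6
AMP,ribose,A,ab,vacuum,beta,1.0,-18.3,-17.3,-12.6
GMP,ribose,G,ab,vacuum,alpha,6.2,-9.8,-3.6,-9.5
GMP,ribose,G,ab,vacuum,beta,1.9,-15.1,-13.1,-9.5
CMP,ribose,C,ab,vacuum,alpha,1.9,-5.4,-3.5,-11.8
CMP,ribose,C,ab,vacuum,beta,3.4,-18.8,-15.3,-11.8
TMP,ribose,T,ab,vacuum,alpha,6.7,-8.9,-2.2,-5.3
TMP,ribose,T,ab,vacuum,beta,5.7,-13.2,-7.5,-5.3
UMP,ribose,U,ab,vacuum,alpha,6.8,-9.5,-2.7,-15.2
UMP,ribose,U,ab,vacuum,beta,5.8,-23.8,-18.0,-15.2
dAMP,deoxyribose,A,ab,aqueous,alpha,4.5,0.6,5.0,-0.8
dAMP,deoxyribose,A,ab,aqueous,beta,2.6,1.6,4.2,-0.8
dGMP,deoxyribose,G,ab,aqueous,alpha,4.3,0.6,4.9,-1.5
dGMP,deoxyribose,G,ab,aqueous,beta,3.0,0.4,3.4,-1.5
dCMP,deoxyribose,C,ab,aqueous,alpha,5.9,2.6,8.5,-3.9
dCMP,deoxyribose,C,ab,aqueous,beta,4.5,0.1,4.6,-3.9
dTMP,deoxyribose,T,ab,aqueous,alpha,6.3,2.1,8.3,-2.9
dTMP,deoxyribose,T,ab,aqueous,beta,4.9,0.5,5.4,-2.9
dUMP,deoxyribose,U,ab,aqueous,alpha,6.3,2.2,8.5,-4.0
dUMP,deoxyribose,U,ab,aqueous,beta,5.0,-0.5,4.6,-4.0
AMP,ribose,A,ab,aqueous,alpha,3.7,2.4,6.1,-0.4
AMP,ribose,A,ab,aqueous,beta,3.9,1.8,5.7,-0.4
GMP,ribose,G,ab,aqueous,alpha,4.3,3.4,7.7,-2.8
GMP,ribose,G,ab,aqueous,beta,4.4,0.6,4.9,-2.8
CMP,ribose,C,ab,aqueous,alpha,3.5,3.1,8.6,-5.1
CMP,ribose,C,ab,aqueous,beta,2.7,0.8,3.5,-5.1
TMP,ribose,T,ab,aqueous,alpha,7.7,2.8,10.5,-4.7
TMP,ribose,T,ab,aqueous,beta,5.9,-0.1,5.8,-4.7
UMP,ribose,U,ab,aqueous,alpha,6.9,2.6,9.5,-4.1
UMP,ribose,U,ab,aqueous,beta,5.8,-0.4,5.4,-4.1
dAMP,deoxyribose,A,cd,vacuum,alpha,-3.1,-3.7,-6.8,2.9
dAMP,deoxyribose,A,cd,vacuum,beta,-8.5,4.6,-3.9,2.9
dGMP,deoxyribose,G,cd,vacuum,alpha,-3.1,-3.2,-6.3,-5.7
dGMP,deoxyribose,G,cd,vacuum,beta,-8.5,-3.5,-12.0,-5.7
dCMP,deoxyribose,C,cd,vacuum,alpha,-3.1,4.7,1.5,-14.3
dCMP,deoxyribose,C,cd,vacuum,beta,-8.5,-4.2,-12.7,-14.3
dTMP,deoxyribose,T,cd,vacuum,alpha,-3.1,1.4,-1.7,-12.0
dTMP,deoxyribose,T,cd,vacuum,beta,-8.5,-5.2,-13.7,-12.0
dUMP,deoxyribose,U,cd,vacuum,alpha,-3.1,0.7,-2.4,-12.4
dUMP,deoxyribose,U,cd,vacuum,beta,-8.5,-6.3,-14.8,-12.4
AMP,ribose,A,cd,vacuum,alpha,-5.2,0.8,-4.4,-0.2
AMP,ribose,A,cd,vacuum,beta,-9.8,5.1,-4.6,-0.2
GMP,ribose,G,cd,vacuum,alpha,-5.2,-7.1,-12.3,-1.8
GMP,ribose,G,cd,vacuum,beta,-9.8,-4.4,-14.1,-1.8
CMP,ribose,C,cd,vacuum,alpha,-5.2,2.8,-2.4,-4.4
CMP,ribose,C,cd,vacuum,beta,-9.8,3.0,-6.8,-4.4
TMP,ribose,T,cd,vacuum,alpha,-5.2,-8.4,-13.6,4.8
TMP,ribose,T,cd,vacuum,beta,-9.8,1.0,-8.8,4.8
UMP,ribose,U,cd,vacuum,alpha,-5.2,-9.2,-14.4,8.4
UMP,ribose,U,cd,vacuum,beta,-9.8,3.7,-6.0,8.4
dAMP,deoxyribose,A,cd,aqueous,alpha,2.0,5.0,7.0,-1.7
dAMP,deoxyribose,A,cd,aqueous,beta,-2.3,7.6,5.3,-1.7
dGMP,deoxyribose,G,cd,aqueous,alpha,2.0,4.6,6.6,-2.0
dGMP,deoxyribose,G,cd,aqueous,beta,-2.3,6.9,4.6,-2.0
dCMP,deoxyribose,C,cd,aqueous,alpha,2.0,6.2,8.2,-2.5
dCMP,deoxyribose,C,cd,aqueous,beta,-2.3,7.9,5.6,-2.5
dTMP,deoxyribose,T,cd,aqueous,alpha,2.0,6.7,8.7,-1.6
dTMP,deoxyribose,T,cd,aqueous,beta,-2.3,9.4,7.1,-1.6
dUMP,deoxyribose,U,cd,aqueous,alpha,2.0,6.4,8.4,-1.9
dUMP,deoxyribose,U,cd,aqueous,beta,-2.3,8.7,6.4,-1.9
AMP,ribose,A,cd,aqueous,alpha,1.8,5.7,7.5,-2.8
AMP,ribose,A,cd,aqueous,beta,-0.9,5.7,4.8,-2.8
GMP,ribose,G,cd,aqueous,alpha,1.8,6.0,7.9,-2.1
GMP,ribose,G,cd,aqueous,beta,-0.9,6.6,5.7,-2.1
CMP,ribose,C,cd,aqueous,alpha,1.8,5.5,7.3,-2.2
CMP,ribose,C,cd,aqueous,beta,-0.9,6.0,5.1,-2.2
TMP,ribose,T,cd,aqueous,alpha,1.8,8.4,10.3,-1.8
TMP,ribose,T,cd,aqueous,beta,-0.9,9.4,8.5,-1.8
UMP,ribose,U,cd,aqueous,alpha,1.8,8.1,9.9,-3.8
UMP,ribose,U,cd,aqueous,beta,-0.9,7.0,6.1,-3.8
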