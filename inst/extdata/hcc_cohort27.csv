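sample_id,tissue_class,etiology,tnm_stage,tnm,differentiation,gender,multifocality,vascularization,tumor_size_class,cirrhosis_flag
HCC_HCV_01,HCC,HCV,T1,T1N0Mx,1,Male,yes,yes,>5 cm,yes
HCC_HCV_02,HCC,HCV,T1,T1N0Mx,1,Male,yes,yes,>5 cm,yes
HCC_HCV_03,HCC,HCV,T1,T1N0Mx,1,Male,yes,yes,>5 cm,yes
HCC_HCV_04,HCC,HCV,T1,T1N0Mx,1,Male,yes,yes,>5 cm,yes
HCC_HCV_05,HCC,HCV,T2,T2N0Mx,2,Male,no,yes,<5 cm,yes
HCC_HCV_06,HCC,HCV,T2,T2N0Mx,2,Male,no,yes,<5 cm,yes
HCC_HCV_07,HCC,HCV,T2,T2N0Mx,2,Male,no,no,<5 cm,yes
HCC_HCV_08,HCC,HCV,T2,T2N0Mx,2,Male,no,no,<5 cm,yes
HCC_HCV_09,HCC,HCV,T3,T3N0Mx,2,Male,no,no,<5 cm,yes
HCC_HCV_10,HCC,HCV,T3,T3N0Mx,2,Female,no,no,<5 cm,yes
HCC_HCV_11,HCC,HCV,T3,T3N0Mx,2,Female,no,no,<5 cm,yes
HCC_HCV_12,HCC,HCV,T3,T3N0Mx,3,Female,no,no,<5 cm,yes
HCC_EtOH_01,HCC,EtOH,T1,T1N0Mx,1,Male,yes,yes,>5 cm,yes
HCC_EtOH_02,HCC,EtOH,T1,T1N0Mx,1,Male,yes,yes,>5 cm,yes
HCC_EtOH_03,HCC,EtOH,T1,T1N0Mx,1,Male,yes,yes,>5 cm,yes
HCC_EtOH_04,HCC,EtOH,T1,T1N0Mx,1,Male,yes,yes,>5 cm,yes
HCC_EtOH_05,HCC,EtOH,T1,T1N0Mx,1,Male,yes,yes,>5 cm,yes
HCC_EtOH_06,HCC,EtOH,T1,T1N0Mx,1,Male,yes,yes,>5 cm,yes
HCC_EtOH_07,HCC,EtOH,T2,T2N0Mx,2,Male,yes,yes,>5 cm,yes
HCC_EtOH_08,HCC,EtOH,T2,T2N0Mx,2,Male,yes,yes,<5 cm,yes
HCC_EtOH_09,HCC,EtOH,T2,T2N0Mx,2,Male,yes,no,<5 cm,yes
HCC_EtOH_10,HCC,EtOH,T3,T3N0Mx,2,Male,no,no,<5 cm,yes
HCC_EtOH_11,HCC,EtOH,T3,T3N0Mx,2,Male,no,no,<5 cm,yes
HCC_EtOH_12,HCC,EtOH,T3,T3N0Mx,2,Male,no,no,<5 cm,yes
HCC_EtOH_13,HCC,EtOH,T3,T3N0Mx,2,Female,no,no,<5 cm,yes
HCC_EtOH_14,HCC,EtOH,T3,T3N0Mx,3,Female,no,no,<5 cm,yes
HCC_EtOH_15,HCC,EtOH,T4,T4N0Mx,3,Female,no,no,<5 cm,no
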