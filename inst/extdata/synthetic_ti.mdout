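
          -------------------------------------------------------
          Amber-style TI output (synthetic fixture for I/O tests)
          -------------------------------------------------------

 NSTEP =      500   TIME(PS) =       1.000  TEMP(K) =   299.85  PRESS =     0.0
 Etot   =    -25080.1234  EKtot   =      4521.7788  EPtot      =    -29601.9022
 DV/DL  =         5.1234
 ------------------------------------------------------------------------------

 NSTEP =     1000   TIME(PS) =       2.000  TEMP(K) =   300.12  PRESS =     0.0
 Etot   =    -25077.5566  EKtot   =      4525.1122  EPtot      =    -29602.6688
 DV/DL  =         4.9876
 ------------------------------------------------------------------------------

 NSTEP =     1500   TIME(PS) =       3.000  TEMP(K) =   300.01  PRESS =     0.0
 Etot   =    -25079.9911  EKtot   =      4523.4455  EPtot      =    -29603.4366
 DV/DL  =        -0.2500
 ------------------------------------------------------------------------------

      A V E R A G E S   O V E R     1500 S T E P S

 NSTEP =     1500   TIME(PS) =       3.000  TEMP(K) =   300.00  PRESS =     0.0
 Etot   =    -25079.2237  EKtot   =      4523.4455  EPtot      =    -29602.6692
 DV/DL  =         3.2870
 ------------------------------------------------------------------------------

      R M S  F L U C T U A T I O N S

 NSTEP =     1500   TIME(PS) =       3.000  TEMP(K) =     0.11  PRESS =     0.0
 Etot   =         1.2295  EKtot   =         1.6672  EPtot      =         0.7702
 DV/DL  =         2.6901
 ------------------------------------------------------------------------------
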