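MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF tf_a
letter-probability matrix: alength= 4 w= 8 nsites= 50 E= 0
 0.072442 0.095003 0.028205 0.804351
 0.070446 0.079798 0.804927 0.044828
 0.782296 0.030407 0.121446 0.065851
 0.009292 0.825163 0.086502 0.079043
 0.090341 0.098623 0.020311 0.790726
 0.035769 0.827508 0.081436 0.055288
 0.826937 0.075843 0.056524 0.040695
 0.025339 0.095397 0.844087 0.035177

MOTIF tf_b
letter-probability matrix: alength= 4 w= 10 nsites= 50 E= 0
 0.012504 0.029853 0.902460 0.055183
 0.054831 0.036722 0.760824 0.147622
 0.031328 0.090355 0.815593 0.062724
 0.055880 0.828986 0.059199 0.055935
 0.062212 0.141658 0.775594 0.020536
 0.053910 0.071735 0.810491 0.063864
 0.075632 0.053598 0.823887 0.046883
 0.068980 0.021334 0.861175 0.048510
 0.092138 0.827405 0.055149 0.025308
 0.027543 0.851594 0.064258 0.056605

MOTIF tf_c
letter-probability matrix: alength= 4 w= 10 nsites= 50 E= 0
 0.064365 0.061322 0.068077 0.806237
 0.045904 0.018105 0.050166 0.885825
 0.114487 0.143447 0.734545 0.007521
 0.840011 0.028998 0.048599 0.082392
 0.025162 0.853434 0.063742 0.057663
 0.114268 0.081114 0.773889 0.030729
 0.155810 0.061096 0.176891 0.606203
 0.105340 0.772515 0.077783 0.044362
 0.834835 0.105327 0.034877 0.024961
 0.022418 0.079181 0.068082 0.830319

MOTIF tf_d
letter-probability matrix: alength= 4 w= 8 nsites= 50 E= 0
 0.029360 0.873262 0.057480 0.039898
 0.896272 0.029446 0.016841 0.057441
 0.041765 0.865702 0.043394 0.049140
 0.046920 0.018828 0.889312 0.044939
 0.043667 0.025232 0.051580 0.879520
 0.053328 0.054198 0.834309 0.058166
 0.780945 0.044144 0.156451 0.018460
 0.040452 0.819975 0.081679 0.057894

MOTIF tf_e
letter-probability matrix: alength= 4 w= 10 nsites= 50 E= 0
 0.753097 0.106955 0.088547 0.051401
 0.782476 0.050059 0.102211 0.065254
 0.049935 0.044577 0.011553 0.893936
 0.026666 0.097175 0.040263 0.835896
 0.022403 0.128484 0.770264 0.078849
 0.016263 0.905979 0.039918 0.037840
 0.772588 0.075992 0.089043 0.062377
 0.056215 0.208592 0.031106 0.704087
 0.028429 0.881608 0.064672 0.025291
 0.801705 0.069114 0.070773 0.058408

MOTIF tf_f
letter-probability matrix: alength= 4 w= 11 nsites= 50 E= 0
 0.023158 0.068505 0.837609 0.070729
 0.046079 0.047685 0.847577 0.058660
 0.848373 0.075125 0.028058 0.048444
 0.834348 0.032759 0.074320 0.058574
 0.096708 0.032459 0.780564 0.090269
 0.027073 0.017860 0.035176 0.919890
 0.081777 0.050778 0.845084 0.022361
 0.841278 0.025950 0.021378 0.111395
 0.791613 0.084834 0.045503 0.078051
 0.838451 0.035741 0.092367 0.033440
 0.105296 0.799228 0.042722 0.052754

MOTIF tf_g
letter-probability matrix: alength= 4 w= 12 nsites= 50 E= 0
 0.056030 0.045466 0.032816 0.865688
 0.034315 0.040779 0.833016 0.091890
 0.034220 0.067259 0.087144 0.811377
 0.050867 0.037925 0.055983 0.855224
 0.099237 0.038379 0.099227 0.763157
 0.890214 0.039526 0.039110 0.031150
 0.076079 0.794852 0.039212 0.089857
 0.035568 0.087265 0.038264 0.838903
 0.032528 0.064171 0.040941 0.862360
 0.058184 0.051569 0.101843 0.788404
 0.032437 0.074735 0.815300 0.077528
 0.055533 0.082275 0.812362 0.049830

MOTIF tf_h
letter-probability matrix: alength= 4 w= 12 nsites= 50 E= 0
 0.043985 0.827143 0.047669 0.081202
 0.056002 0.690170 0.124660 0.129168
 0.896867 0.028759 0.036875 0.037499
 0.049207 0.082827 0.051482 0.816484
 0.871709 0.033078 0.041294 0.053918
 0.018632 0.073541 0.110120 0.797708
 0.864111 0.070013 0.042127 0.023750
 0.082510 0.062895 0.071564 0.783031
 0.015181 0.027714 0.846953 0.110153
 0.046647 0.009272 0.872842 0.071238
 0.023581 0.817007 0.042074 0.117337
 0.062626 0.813082 0.068508 0.055784

MOTIF tf_i
letter-probability matrix: alength= 4 w= 14 nsites= 50 E= 0
 0.051454 0.055880 0.864860 0.027806
 0.026878 0.883343 0.040670 0.049109
 0.024686 0.060679 0.834411 0.080224
 0.085818 0.826459 0.048809 0.038914
 0.884963 0.056543 0.024938 0.033556
 0.052164 0.027669 0.088295 0.831872
 0.035562 0.079591 0.864114 0.020733
 0.037919 0.767374 0.118894 0.075813
 0.057078 0.077550 0.840843 0.024529
 0.031982 0.742596 0.165936 0.059486
 0.846285 0.016182 0.055065 0.082468
 0.054336 0.096368 0.779535 0.069760
 0.101282 0.015614 0.064541 0.818563
 0.050624 0.114049 0.064087 0.771240

MOTIF tf_j
letter-probability matrix: alength= 4 w= 15 nsites= 50 E= 0
 0.807058 0.104827 0.037740 0.050375
 0.073941 0.089221 0.020852 0.815985
 0.035606 0.063793 0.802727 0.097874
 0.056159 0.866831 0.051959 0.025051
 0.871397 0.040641 0.026389 0.061573
 0.772854 0.049912 0.071926 0.105308
 0.749190 0.048099 0.163545 0.039167
 0.088104 0.032590 0.077452 0.801854
 0.049426 0.798996 0.079147 0.072432
 0.758511 0.047573 0.047542 0.146374
 0.047677 0.857356 0.063191 0.031776
 0.027093 0.055754 0.067350 0.849803
 0.097054 0.029290 0.856416 0.017239
 0.103454 0.078885 0.051086 0.766575
 0.076129 0.060919 0.815657 0.047295

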