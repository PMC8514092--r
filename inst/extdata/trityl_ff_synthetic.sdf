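trityl
 OpenBabel09292619283D

 34 36  0  0  0  0  0  0  0  0999 V2000
    1.1967    0.3135    0.4759 C   0  0  0  0  0  3  0  0  0  0  0  0
    0.6684   -0.7081    1.4344 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3803   -2.0112    1.0219 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0333   -2.9772    1.9702 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0115   -2.6472    3.3257 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2498   -1.3424    3.7373 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5700   -0.3706    2.7920 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3646    1.5295    0.1828 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9285    2.8105    0.2823 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1356    3.9528    0.1616 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2311    3.8288   -0.0732 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7998    2.5632   -0.2106 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0069    1.4189   -0.0856 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.6670    0.3076    0.1691 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.1395    0.5116   -1.1311 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.5148    0.6000   -1.3716 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.4227    0.4797   -0.3184 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.9638    0.2525    0.9696 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.5949    0.1539    1.2125 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4435   -2.2849   -0.0278 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1793   -3.9951    1.6548 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2425   -3.4097    4.0653 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.2286   -1.0826    4.7917 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7961    0.6420    3.1188 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.9879    2.9332    0.4967 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5849    4.9358    0.2740 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8529    4.7178   -0.1389 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8668    2.4674   -0.3979 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4750    0.4418   -0.1779 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.4434    0.6250   -1.9566 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.8778    0.7723   -2.3784 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.4903    0.5704   -0.5052 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.6643    0.1585    1.8000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.2616   -0.0063    2.2357 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  8  1  0  0  0  0
  1 14  1  0  0  0  0
  2  3  1  0  0  0  0
  2  7  2  0  0  0  0
  3  4  2  0  0  0  0
  3 20  1  0  0  0  0
  4  5  1  0  0  0  0
  4 21  1  0  0  0  0
  5  6  2  0  0  0  0
  5 22  1  0  0  0  0
  6  7  1  0  0  0  0
  6 23  1  0  0  0  0
  7 24  1  0  0  0  0
  8  9  1  0  0  0  0
  8 13  2  0  0  0  0
  9 10  2  0  0  0  0
  9 25  1  0  0  0  0
 10 11  1  0  0  0  0
 10 26  1  0  0  0  0
 11 12  2  0  0  0  0
 11 27  1  0  0  0  0
 12 13  1  0  0  0  0
 12 28  1  0  0  0  0
 13 29  1  0  0  0  0
 14 15  1  0  0  0  0
 14 19  2  0  0  0  0
 15 16  2  0  0  0  0
 15 30  1  0  0  0  0
 16 17  1  0  0  0  0
 16 31  1  0  0  0  0
 17 18  2  0  0  0  0
 17 32  1  0  0  0  0
 18 19  1  0  0  0  0
 18 33  1  0  0  0  0
 19 34  1  0  0  0  0
M  END
$$$$
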