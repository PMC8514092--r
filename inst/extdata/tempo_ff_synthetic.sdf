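TEMPO
 OpenBabel09292619283D

 29 29  0  0  0  0  0  0  0  0999 V2000
    0.9758    0.2311    0.3735 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4868   -0.0314    0.1554 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.2050    0.3050    1.4960 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0371    0.9892   -0.8796 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.6603    0.6639   -2.3191 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0671   -0.7648   -2.6609 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5028   -1.8223   -1.6713 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9928   -2.0322   -1.9605 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.2249   -3.1554   -2.0273 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8597   -1.4001   -0.2913 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.4163   -2.3501    0.6359 O   0  0  0  0  0  1  0  0  0  0  0  0
    0.8208    1.2015    0.8644 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5118   -0.5204    1.0210 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4067    0.2725   -0.5552 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.0496    1.3569    1.7670 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.2885    0.1487    1.4212 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8322   -0.2972    2.3299 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.1341    1.0228   -0.8162 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6880    2.0018   -0.6392 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.1742    1.3585   -2.9945 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.5887    0.8128   -2.4811 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.1651   -0.8131   -2.6666 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7469   -0.9922   -3.6863 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8536   -2.5791   -2.9014 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4460   -1.0952   -2.0765 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4969   -2.6189   -1.1817 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.0975   -3.3979   -3.0894 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8306   -4.0046   -1.4567 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.3031   -3.0901   -1.8359 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1 12  1  0  0  0  0
  1 13  1  0  0  0  0
  1 14  1  0  0  0  0
  2  3  1  0  0  0  0
  2  4  1  0  0  0  0
  2 10  1  0  0  0  0
  3 15  1  0  0  0  0
  3 16  1  0  0  0  0
  3 17  1  0  0  0  0
  4  5  1  0  0  0  0
  4 18  1  0  0  0  0
  4 19  1  0  0  0  0
  5  6  1  0  0  0  0
  5 20  1  0  0  0  0
  5 21  1  0  0  0  0
  6  7  1  0  0  0  0
  6 22  1  0  0  0  0
  6 23  1  0  0  0  0
  7  8  1  0  0  0  0
  7  9  1  0  0  0  0
  7 10  1  0  0  0  0
  8 24  1  0  0  0  0
  8 25  1  0  0  0  0
  8 26  1  0  0  0  0
  9 27  1  0  0  0  0
  9 28  1  0  0  0  0
  9 29  1  0  0  0  0
 10 11  1  0  0  0  0
M  END
$$$$
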