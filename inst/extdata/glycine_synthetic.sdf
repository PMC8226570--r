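glycine_synthetic
  porinperm synthetic zwitterionic glycine conformer (illustrative fixture)

 10  9  0  0  0  0  0  0  0  0999 V2000
    0.9358    0.0788    0.0903 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4340    1.2506    0.9639 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8368    1.2700    0.9968 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.3084    1.9735    1.4859 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.4447    0.0411    0.0624 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.6072    0.1938   -0.9455 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6069   -0.8810    0.4960 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7399    0.9842   -0.2298 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8677   -0.7004   -0.4903 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7397    0.0305    1.0497 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  2  4  1  0  0  0  0
  1  5  1  0  0  0  0
  1  6  1  0  0  0  0
  1  7  1  0  0  0  0
  5  8  1  0  0  0  0
  5  9  1  0  0  0  0
  5 10  1  0  0  0  0
M  END
>  <ATOM_PARTIAL_CHARGES>
0.3970 0.9060 -0.9000 -0.9000 -0.8530 0.0000 0.0000 0.4500 0.4500 0.4500

$$$$
glycine_synthetic
  porinperm synthetic zwitterionic glycine conformer (illustrative fixture)

 10  9  0  0  0  0  0  0  0  0999 V2000
    0.9358    0.0788    0.0903 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4340    1.2506    0.9639 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2824    0.8753    2.1691 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.2590    2.3439    0.3863 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.4447    0.0411    0.0624 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.6072    0.1938   -0.9455 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6069   -0.8810    0.4960 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7399    0.9842   -0.2298 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8677   -0.7004   -0.4903 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7397    0.0305    1.0497 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  2  4  1  0  0  0  0
  1  5  1  0  0  0  0
  1  6  1  0  0  0  0
  1  7  1  0  0  0  0
  5  8  1  0  0  0  0
  5  9  1  0  0  0  0
  5 10  1  0  0  0  0
M  END
>  <ATOM_PARTIAL_CHARGES>
0.3970 0.9060 -0.9000 -0.9000 -0.8530 0.0000 0.0000 0.4500 0.4500 0.4500

$$$$
glycine_synthetic
  porinperm synthetic zwitterionic glycine conformer (illustrative fixture)

 10  9  0  0  0  0  0  0  0  0999 V2000
    0.9358    0.0788    0.0903 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4340    1.2506    0.9639 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2678    2.2102    0.9445 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6655    1.0921    1.5344 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.4447    0.0411    0.0624 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.6072    0.1938   -0.9455 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6069   -0.8810    0.4960 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7399    0.9842   -0.2298 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8677   -0.7004   -0.4903 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7397    0.0305    1.0497 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  2  4  1  0  0  0  0
  1  5  1  0  0  0  0
  1  6  1  0  0  0  0
  1  7  1  0  0  0  0
  5  8  1  0  0  0  0
  5  9  1  0  0  0  0
  5 10  1  0  0  0  0
M  END
>  <ATOM_PARTIAL_CHARGES>
0.3970 0.9060 -0.9000 -0.9000 -0.8530 0.0000 0.0000 0.4500 0.4500 0.4500

$$$$
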