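case_id,segment,obstetrician1,obstetrician2,obstetrician3
1,Initial hour,80,80,80
2,Initial hour,65,66,70
3,Initial hour,65,66,70
4,Initial hour,63,67,65
5,Initial hour,82,83,85
6,Initial hour,75,76,75
7,Initial hour,80,81,85
8,Initial hour,84,85,80
9,Initial hour,100,102,105
10,Initial hour,82,82,80
11,Initial hour,67,65,70
12,Initial hour,75,74,87
13,Initial hour,70,70,70
14,Last hour,78,75,75
15,Last hour,90,90,100
16,Last hour,70,67,70
17,Last hour,70,65,65
18,Last hour,87,87,90
19,Last hour,72,73,75
20,Last hour,75,75,75
21,Last hour,100,98,100
22,Last hour,110,108,110
23,Last hour,103,103,100
24,Last hour,80,80,100
25,Last hour,98,100,100
26,Last hour,70,70,65
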