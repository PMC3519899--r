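case_id,volume_manual_mm3,volume_auto_mm3,voxels_manual,voxels_auto,dsc_percent
1,6568.69,7195,72461,79370,85.87
2,4150.91,5427.76,4457,5828,84.36
3,7180.44,6481.12,35701,32224,82.11
4,5538.25,5964.5,61094,65796,85.1
5,3230.26,2950.45,22027,20119,77.51
6,9858.4,10410.8,67224,70991,84.46
7,6111.79,5274.89,52500,45311,75.6
8,5082.1,4169.32,56062,45993,80.1
9,15271.1,15838.9,104133,108005,83.41
10,757.007,1016.58,5162,6932,81.21
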