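trait	n
MIP-1a	3522
MIP-1b	8243
Eotaxin	8153
MCP-1	8293
MCP-3	843
MIG	3685
IP-10	3685
CTACK	3631
RANTES	3421
GROa	3505
SDF-1a	5998
SCGF-b	3682
PDGFbb	8293
SCF	8290
GCSF	7904
VEGF	7118
HGF	8292
MCSF	839
bNGF	3531
bFGF	7565
IL-1ra	3638
IL-1b	3309
IL-2ra	3677
IL-2	3475
IL-4	8214
IL-5	3364
IL-6	8189
IL-7	3409
IL-8	3526
IL-9	3634
IL-10	7681
IL-12p70	8270
IL-13	3557
IL-16	3483
IL-17	7760
IL-18	3636
TRAIL	8186
IFN-g	7701
MIF	3494
TNF-a	3454
TNF-b	1559
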