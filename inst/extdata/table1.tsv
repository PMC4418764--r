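grade	direction	mirna	common
GI	up	hsa-miR-452	1
GI	up	hsa-miR-487a	1
GI	up	hsa-miR-491-3p	1
GI	up	hsa-miR-200c	1
GI	up	hsa-miR-155	0
GI	up	hsa-miR-340	0
GI	up	hsa-miR-365	0
GI	up	hsa-miR-493	0
GI	up	hsa-miR-519e	0
GI	up	hsa-miR-520a-5p	0
GI	up	hsa-miR-768-3p	0
GI	up	hsa-miR-297	0
GII	up	hsa-miR-452	1
GII	up	hsa-miR-487a	1
GII	up	hsa-miR-491-3p	1
GII	up	hsa-miR-200c	1
GII	up	hsa-miR-297	0
GII	up	hsa-miR-299-5p	0
GII	up	hsa-miR-29b-1	0
GII	up	hsa-miR-32	0
GII	up	hsa-miR-369-3p	0
GII	up	hsa-miR-423-5p	0
GII	up	hsa-miR-486-5p	0
GII	up	hsa-miR-519d	0
GII	up	hsa-miR-574-5p	0
GII	up	hsa-miR-662	0
GII	up	hsa-miR-766	0
GII	up	hsa-miR-768-3p	0
GII	up	hsa-miR-92b	0
GII	up	miRplus-17858	0
GIII	up	hsa-miR-452	1
GIII	up	hsa-miR-487a	1
GIII	up	hsa-miR-491-3p	1
GIII	up	hsa-miR-200c	1
GIII	up	hsa-miR-125a-5p	0
GIII	up	hsa-miR-183	0
GIII	up	hsa-miR-184	0
GIII	up	hsa-miR-208	0
GIII	up	hsa-miR-214	0
GIII	up	hsa-miR-381	0
GIII	up	hsa-miR-520a-5p	0
GIII	up	hsa-miR-526b	0
GIII	up	hsa-miR-551a	0
GIII	up	hsa-miR-583	0
GIII	up	hsa-miR-766	0
GIII	up	hsa-miR-768-3p	0
GIII	up	hsa-miR-890	0
GIII	up	hsa-miR-891a	0
GIII	up	miRplus-17955	0
GI	down	hsa-miR-125b	1
GI	down	hsa-miR-142-3p	1
GI	down	hsa-miR-199a-5p	1
GI	down	hsa-miR-22	1
GI	down	hsa-miR-299-3p	1
GI	down	hsa-miR-29a	1
GI	down	hsa-miR-429	1
GI	down	hsa-miR-532-5p	1
GI	down	hsa-miR-148a	0
GI	down	hsa-miR-632	0
GI	down	hsa-miR-637	0
GI	down	miRplus-17952	0
GII	down	hsa-miR-125b	1
GII	down	hsa-miR-142-3p	1
GII	down	hsa-miR-199a-5p	1
GII	down	hsa-miR-22	1
GII	down	hsa-miR-299-3p	1
GII	down	hsa-miR-29a	1
GII	down	hsa-miR-429	1
GII	down	hsa-miR-532-5p	1
GII	down	hsa-miR-147b	0
GII	down	hsa-miR-23b	0
GII	down	hsa-miR-26a	0
GII	down	hsa-miR-29b	0
GII	down	hsa-miR-571	0
GII	down	hsa-miR-637	0
GII	down	hsa-miR-99a	0
GII	down	hsa-miR-99b	0
GII	down	miRplus-17952	0
GIII	down	hsa-miR-125b	1
GIII	down	hsa-miR-142-3p	1
GIII	down	hsa-miR-199a-5p	1
GIII	down	hsa-miR-22	1
GIII	down	hsa-miR-299-3p	1
GIII	down	hsa-miR-29a	1
GIII	down	hsa-miR-429	1
GIII	down	hsa-miR-532-5p	1
GIII	down	hsa-miR-143	0
GIII	down	hsa-miR-23b	0
GIII	down	hsa-miR-26a	0
GIII	down	hsa-miR-30b	0
GIII	down	hsa-miR-622	0
GIII	down	hsa-miR-765	0
GIII	down	hsa-let-7g	0
GIII	down	hsa-let-7i	0
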