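MIMAT0000250	hsa-miR-139;hsa-miR-139-5p;
MIMAT0004552	hsa-miR-139-3p;
MIMAT0000066	hsa-let-7e;hsa-let-7e-5p;
MIMAT0004485	hsa-let-7e*;hsa-let-7e-3p;
MIMAT0000423	hsa-miR-125b;hsa-miR-125b-5p;
MIMAT0000074	hsa-miR-19b;hsa-miR-19b-3p;
MIMAT0004597	hsa-miR-140*;hsa-miR-140-3p;
MIMAT0000689	hsa-miR-99b;hsa-miR-99b-5p;
MIMAT0000731	hsa-miR-378;hsa-miR-378a-3p;
MIMAT0022837	hsa-miR-378;hsa-miR-378a-5p;
MIMAT0000685	hsa-miR-34b;hsa-miR-34b-5p;
MIMAT0004676	hsa-miR-34b;hsa-miR-34b-3p;
MIMAT0000098	hsa-miR-100;hsa-miR-100-5p;
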