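mirna	gene	evidence
hsa-let-7c-5p	FASLG	reported
hsa-let-7c-5p	TNFSF10	reported
hsa-let-7c-5p	OSM	reported
hsa-miR-199a-5p	GZMB	reported
hsa-miR-199b-5p	GZMB	reported
hsa-miR-28-5p	PRF1	synthetic
hsa-miR-23b-3p	TNF	synthetic
hsa-miR-30c-5p	CD40LG	synthetic
hsa-miR-155-5p	OSM	synthetic
hsa-miR-21-5p	TNF	synthetic
hsa-miR-146a-5p	CD40LG	synthetic
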