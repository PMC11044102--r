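# analyte parameter table
# kinds: lss (p1 = k0, p2 = S) | adsorption (p1 = k100, p2 = n)
# van Deemter: a (um), b (um mm/s), c (um s/mm)
"name","d1_kind","d1_p1","d1_p2","d1_vd_a","d1_vd_b","d1_vd_c","d2_kind","d2_p1","d2_p2","d2_vd_a","d2_vd_b","d2_vd_c"
"syn01","adsorption",0.177830233077982,1.30010424980045,2.22625963961138,6.3322001735024,0.815466421579919,"lss",5.49605030889497,33.372701676022,2.88290412946136,2.45905202596442,0.493981460406785
"syn02","adsorption",0.0563600004414235,1.95150583880146,3.35510763414002,2.79258978494229,0.344408187689321,"lss",169.305996366263,22.5070252640094,2.42734588679657,3.24647904150851,1.48027074460373
"syn03","adsorption",0.108109229608472,0.536518434604572,2.33265288748904,2.95279384167779,0.315505173498865,"lss",7.06058508642979,13.7955533156506,2.45430484403185,2.01195297940815,0.523226196792333
"syn04","adsorption",0.217978398703856,1.85875691271353,2.02456746173444,5.12787842882993,0.737513251693067,"lss",12.4272139559943,36.7215707253518,3.51617740623309,4.9401667151247,0.561576914822763
"syn05","adsorption",0.107004484277822,0.629833942502043,3.69273646894982,2.15067471081877,0.909721086020595,"lss",16.12807798488,24.0675818694934,2.97776704833846,7.32603457734697,0.920666580806556
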