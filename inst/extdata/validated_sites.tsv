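gene	primer	condition	predicted	validated
yejG	P1	aerobic	2276288	2276299
yejG	P2	aerobic	2276432	2276419
spr	P1	aerobic	2267945	2267942
spr	P2	aerobic	2267825	2267833
dcuA	P1	anaerobic	4364876	4364866
dcuA	P2	anaerobic	4364975	4364974
aroL	P1	anaerobic	405583	405579
aroL	P2	anaerobic	405489	405504
serC	P1	aerobic	956823	956802
serC	NA	aerobic	956789	NA
hybO	P1	anaerobic	3144382	3144385
hybO	NA	anaerobic	3144438	NA
ybgI	P1	aerobic	742036	742030
ybgI	P1b	aerobic	741859	741874
ptsG	P1	aerobic	1157005	1156989
ptsG	P1b	aerobic	1156866	1156849
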