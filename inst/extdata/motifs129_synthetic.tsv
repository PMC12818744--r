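# Synthetic stand-in for the curated list of 129 enriched DPR motifs.
# Contains the motifs named in the study narrative plus constructed
# fillers, assembled so the set reproduces the published summary
# statistics (length distribution 2/54/31/13%; Gly 59%, Pro 47%,
# Ser 29%, Arg 23%, Gln 20%, Tyr 19% membership; 36% embedded;
# 19 RGG-containing motifs).  It is NOT the original supplementary list.
motif	length
HHP	3
QPN	3
AAPA	4
AQQA	4
DDED	4
DDEE	4
DEDD	4
DEED	4
DRGG	4
DSSS	4
EDDE	4
EEDD	4
FGGG	4
GAPG	4
GDRG	4
GGDR	4
GGGR	4
GGGY	4
GGNG	4
GGRG	4
GGRS	4
GGSG	4
GGYG	4
GPGS	4
GPPG	4
GPYG	4
GRGG	4
GRGS	4
GSSG	4
GYGG	4
GYGN	4
HPPP	4
HQQH	4
HQQQ	4
PAPA	4
PGGS	4
PGQQ	4
PGVG	4
PPGG	4
PPPG	4
PPPP	4
PPPS	4
PPQG	4
PPSS	4
PSGP	4
QGPG	4
QQAQ	4
QQGP	4
QQPG	4
QQPP	4
QQQH	4
QQQP	4
QQQQ	4
RGGF	4
RGGG	4
RGGS	4
RGGY	4
RHQQ	4
RQQP	4
RSGG	4
SAPA	4
SGGS	4
SPGG	4
SSAP	4
SSDS	4
TPTT	4
TQQQ	4
VPPP	4
YGGG	4
YGPG	4
YSPS	4
YSPT	4
AAPAP	5
APPPA	5
GDRGG	5
GGDRG	5
GGFGG	5
GGGGF	5
GGGGG	5
GGGGS	5
GGRGG	5
GGRSG	5
GGYGG	5
GPYGG	5
GRGGY	5
GSGGG	5
GVPGV	5
GYGGG	5
HQQQQ	5
PGQQQ	5
PGVGV	5
PPPPP	5
PPPPQ	5
PPQGG	5
PPSSG	5
PRGGF	5
QQGPP	5
QQPPP	5
QQQPP	5
QQQQQ	5
RGGFG	5
RGGPG	5
SAPAP	5
SGGGG	5
SPTSP	5
SRGGS	5
SSDSS	5
TNANT	5
TSPSY	5
VPGVG	5
YGGGS	5
YSPTS	5
GDRGGY	6
GGDRGG	6
GGGGGG	6
GGGRGG	6
GGGYGG	6
GRGGYG	6
PGVGVP	6
PPPPPP	6
PTSPSY	6
QQQQQQ	6
RGGFGG	6
RGGRGG	6
SGGGGS	6
SPTSPS	6
TSPSYS	6
YGPGSG	6
YSPTSP	6
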