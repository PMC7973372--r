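# Default functional gene sets for the panel. These are configuration, not
# code: replace with your own lists as needed. HDR must be a subset of DDR.
DDR: [ATM, ATR, BARD1, BRCA1, BRCA2, BRIP1, CHEK2, ERCC4, FANCA, FANCC, FANCD2,
      FANCG, MLH1, MRE11A, MSH2, MSH6, MUTYH, NBN, PALB2, PMS2, POLD1, POLE,
      RAD50, RAD51, RAD51C, RAD51D, TP53, WRN, XRCC2]
HDR: [ATM, BARD1, BRCA1, BRCA2, BRIP1, MRE11A, NBN, PALB2, RAD50, RAD51,
      RAD51C, RAD51D, XRCC2]
CELL_CYCLE: [ATM, ATR, BUB1B, CDK4, CDKN2A, CHEK2, MEN1, STK11, TP53, TSC2]
# genetic chronic pancreatitis pathway
GCP: [CFTR, CTRC, CPA1, SDHA, SDHB, SDHC, SDHD]
ATM: [ATM]
BRCA1_2: [BRCA1, BRCA2]
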