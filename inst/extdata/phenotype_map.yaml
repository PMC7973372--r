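# Phenotype curation map: phenotype string -> CANCER | CANCER_RISK | OTHER.
# Emulates manual curation of database phenotypes; extend for your snapshots.
Breast cancer: CANCER
Ovarian cancer: CANCER
Colorectal cancer: CANCER
Pancreatic adenocarcinoma: CANCER
Pancreatic cancer susceptibility: CANCER_RISK
Hereditary cancer-predisposing syndrome: CANCER_RISK
Lynch syndrome: CANCER_RISK
Ataxia telangiectasia: CANCER_RISK
Cystic fibrosis: OTHER
Pancreatitis: OTHER
Hereditary pancreatitis: OTHER
Drug metabolism: OTHER
Cardiovascular phenotype: OTHER
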