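list,pattern
death,^death$
death,^sudden death
death,^brain death
death,^cardiac death
covid,covid
malignancy,^metastas
malignancy,^malignant neoplasm
malignancy,neoplasm progression
malignancy,^tumou?r progression
malignancy,^disease progression$
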