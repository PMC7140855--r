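drug_id	n_patients	n_responders	predicted_responders	concordant_responders
cyclophosphamide	96	93	96	93
docetaxel	47	43	47	43
doxorubicin	50	47	50	47
fluorouracil	31	31	31	31
paclitaxel	42	39	42	39
tamoxifen	18	15	18	15
lapatinib	31	8	3	2
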