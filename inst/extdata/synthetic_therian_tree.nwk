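((opossum:55,wallaby:55):105,((armadillo:99,elephant:99):6,(((cat:55,dog:55):40,(horse:77,bull:77):18):5,((mouse:20,rat:20):70,(marmoset:43,(rhesus:29,(chimp:7,human:7):22):14):47):10):5):55):0;
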