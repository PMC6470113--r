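{
  "omega": 0.113,
  "v_pits": 1.5158,
  "source": "Norwegian 15D value algorithm; disutility decrements estimated from VAS valuation data of the Norwegian general adult population (within-dimension tasks 2010, pits task 2015-2016), published at 4-decimal precision"
}
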