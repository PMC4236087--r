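{
 "reference_table": "table5",
 "sizes_list": [
  [
   8,
   8,
   8,
   8
  ],
  [
   10,
   6,
   6,
   10
  ],
  [
   20,
   20,
   10,
   10
  ],
  [
   10,
   20,
   10,
   20
  ]
 ],
 "null": {
  "dist": "normal",
  "mean": [
   0,
   0,
   0,
   0
  ]
 },
 "alternatives": {
  "A": {
   "dist": "normal",
   "mean": [
    0,
    0.2,
    0.5,
    1
   ]
  },
  "B": {
   "dist": "normal",
   "mean": [
    0,
    0.5,
    0.5,
    0.5
   ]
  },
  "C": {
   "dist": "normal",
   "mean": [
    0,
    0,
    0,
    1
   ]
  }
 },
 "alpha": 0.05,
 "b_null": 20000,
 "b_alt": 10000
}
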