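{
 "reference_table": "table7",
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
  "dist": "exponential",
  "mean": [
   1,
   1,
   1,
   1
  ]
 },
 "alternatives": {
  "A": {
   "dist": "exponential",
   "mean": [
    1,
    1.2,
    1.5,
    2
   ]
  },
  "B": {
   "dist": "exponential",
   "mean": [
    1,
    1.5,
    1.5,
    1.5
   ]
  },
  "C": {
   "dist": "exponential",
   "mean": [
    1,
    1,
    1,
    2
   ]
  }
 },
 "alpha": 0.05,
 "b_null": 20000,
 "b_alt": 10000
}
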