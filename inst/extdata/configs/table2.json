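{
 "reference_table": "table2",
 "sizes_list": [
  [
   10,
   10,
   10
  ],
  [
   10,
   15,
   20
  ],
  [
   30,
   20,
   10
  ],
  [
   10,
   20,
   10
  ]
 ],
 "null": {
  "dist": "t3",
  "mean": [
   0,
   0,
   0
  ]
 },
 "alternatives": {
  "a": {
   "dist": "t3",
   "mean": [
    0,
    0.5,
    1
   ]
  },
  "b": {
   "dist": "t3",
   "mean": [
    0,
    1,
    1
   ]
  },
  "c": {
   "dist": "t3",
   "mean": [
    0,
    0,
    1
   ]
  },
  "d": {
   "dist": "t3",
   "mean": [
    0,
    1,
    0.5
   ]
  }
 },
 "alpha": 0.05,
 "b_null": 20000,
 "b_alt": 10000
}
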