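{
 "reference_table": "table1",
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
  "dist": "normal",
  "mean": [
   0,
   0,
   0
  ]
 },
 "alternatives": {
  "a": {
   "dist": "normal",
   "mean": [
    0,
    0.5,
    1
   ]
  },
  "b": {
   "dist": "normal",
   "mean": [
    0,
    1,
    1
   ]
  },
  "c": {
   "dist": "normal",
   "mean": [
    0,
    0,
    1
   ]
  },
  "d": {
   "dist": "normal",
   "mean": [
    0,
    1,
    0.5
   ]
  },
  "e": {
   "dist": "normal",
   "mean": [
    0,
    0.6,
    1
   ],
   "sd": [
    3,
    2,
    1
   ]
  }
 },
 "alpha": 0.05,
 "b_null": 20000,
 "b_alt": 10000
}
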