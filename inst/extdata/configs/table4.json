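{
 "reference_table": "table4",
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
  "dist": [
   "normal",
   "exponential",
   "exponential"
  ],
  "mean": [
   1,
   1,
   1
  ]
 },
 "calibration": {
  "dist": "normal",
  "mean": [
   0,
   0,
   0
  ]
 },
 "alternatives": {
  "a": {
   "dist": [
    "normal",
    "exponential",
    "exponential"
   ],
   "mean": [
    1,
    1.5,
    2
   ]
  },
  "b": {
   "dist": [
    "normal",
    "exponential",
    "exponential"
   ],
   "mean": [
    1,
    2,
    2
   ]
  },
  "c": {
   "dist": [
    "normal",
    "exponential",
    "exponential"
   ],
   "mean": [
    1,
    1,
    2
   ]
  },
  "d": {
   "dist": [
    "normal",
    "exponential",
    "exponential"
   ],
   "mean": [
    1,
    2,
    1.5
   ]
  }
 },
 "alpha": 0.05,
 "b_null": 20000,
 "b_alt": 10000
}
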