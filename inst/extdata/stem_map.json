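{
  "reading": "read",
  "reads": "read",
  "finding": "find",
  "finds": "find",
  "found": "find",
  "seeing": "see",
  "sees": "see",
  "saw": "see",
  "identifying": "identify",
  "identifies": "identify",
  "identified": "identify",
  "operating": "operate",
  "operates": "operate",
  "operated": "operate",
  "buses": "bus",
  "busses": "bus",
  "label": "labels",
  "tv": "tv",
  "watching": "watch",
  "watched": "watch",
  "watches": "watch",
  "using": "use",
  "used": "use",
  "uses": "use",
  "looking": "look",
  "looked": "look",
  "looks": "look",
  "checking": "check",
  "checked": "check",
  "checks": "check",
  "signs": "sign",
  "making": "make",
  "made": "make"
}
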