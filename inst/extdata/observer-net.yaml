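places:
  p1: 1.0
  p2: 0.0
  p3: 0.0
  p4: 0.0
  p5: 0.0
  p6: 0.0
transitions:
  t1: 0.0
  t2: 0.0
  t3: 0.0
ehandlers:
  v1:
    from:
      a: p1
    to:
      b: p2
    link:
      x: t1
  v2:
    from:
      a: p2
    to:
      b: p3
  v3:
    from:
      a: p3
    to:
      b: p4
    link:
      x: t2
  v4:
    from:
      a: p2
    to:
      b: p5
    link:
      x: t2
    rel:
    - a = x
    - x <= b <= 2x
  v5:
    from:
      a: p5
    to:
      b: p6
    link:
      x: t3
    rel:
    - a = 2x
    - b = x
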