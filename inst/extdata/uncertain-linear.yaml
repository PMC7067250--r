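places:
  p1: 4.0
  p2: 0.0
  p3: 0.0
transitions:
  t1:
  - 1.0
  - 1.5
  t2: 0.0
  t3: 0.0
  t4: 2.0
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
      b: p1
    link:
      x: t2
  v3:
    from:
      a: p1
    to:
      b: p3
    link:
      x: t3
  v4:
    from:
      a: p3
    to:
      b: p1
    link:
      x: t4
shandlers:
  s2:
    to:
      'y': t2
    link:
      u: p2
  s3:
    to:
      r: t3
    link:
      a: p1
    rel:
    - 0.9a <= r <= 1.1a
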