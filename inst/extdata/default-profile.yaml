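# Built-in configuration profile of the fuzzy edge detection pipeline.
# All grey levels are on the 8-bit scale [0, 255].

detector:
  input:
    Lower:  {type: trapezoid, params: [0, 0, 25, 75]}
    Higher: {type: trapezoid, params: [25, 75, 255, 255]}
  output:
    NonEdge: {type: gaussian, m: 10,  d: 3.5}
    Edge:    {type: gaussian, m: 245, d: 3.5}
  universe: {lo: 0, hi: 255, n: 512}
  threshold: 127.5
  # mask index convention: 1=NW 2=N 3=NE 4=W 5=E 6=SW 7=S 8=SE
  # (quoted: bare N/Y are YAML booleans)
  neighbors: ["NW", "N", "NE", "W", "E", "SW", "S", "SE"]
  # knowledge base: two adjacent Higher differences plus one opposite Lower
  rules:
    - {higher: [1, 2], lower: [8], consequent: Edge}
    - {higher: [1, 4], lower: [8], consequent: Edge}
    - {higher: [2, 3], lower: [8], consequent: Edge}
    - {higher: [4, 6], lower: [8], consequent: Edge}
    - {higher: [1, 2], lower: [7], consequent: Edge}
    - {higher: [1, 4], lower: [7], consequent: Edge}
    - {higher: [2, 3], lower: [7], consequent: Edge}
    - {higher: [4, 6], lower: [7], consequent: Edge}
    - {higher: [1, 2], lower: [5], consequent: Edge}
    - {higher: [1, 4], lower: [5], consequent: Edge}
    - {higher: [2, 3], lower: [5], consequent: Edge}
    - {higher: [4, 6], lower: [5], consequent: Edge}

contrast:
  input:
    Darker:   {type: trapezoid, params: [0, 0, 80, 127]}
    Grey:     {type: trapezoid, params: [105, 124, 131, 150]}
    Brighter: {type: trapezoid, params: [128, 175, 255, 255]}
  output:
    Darkest:   {type: gaussian, m: 5,     d: 20}
    Grey:      {type: gaussian, m: 127.5, d: 20}
    Brightest: {type: gaussian, m: 250,   d: 20}
  rules:
    Darker: Darkest
    Grey: Grey
    Brighter: Brightest

noise:
  psnr: 25
  seed: 1
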