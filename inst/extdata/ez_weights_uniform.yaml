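# PLACEHOLDER weighting scheme: every endpoint weighted 1.0.
# The EZ Metric is a weighted sum of binary endpoint calls over 4 endpoints
# scored at 24 hours post fertilization and 17 scored at 120 hours post
# fertilization. Real analyses should substitute the weighting scheme
# appropriate to their assay battery; weights are user configuration, not
# package constants.
endpoints:
  MO24:   {weight: 1.0, group: 24hpf}   # mortality, 24 hpf
  DP24:   {weight: 1.0, group: 24hpf}   # delayed development, 24 hpf
  SM24:   {weight: 1.0, group: 24hpf}   # absent spontaneous movement, 24 hpf
  NC24:   {weight: 1.0, group: 24hpf}   # notochord malformation, 24 hpf
  MORT:   {weight: 1.0, group: 120hpf}  # cumulative mortality, 120 hpf
  YSE:    {weight: 1.0, group: 120hpf}  # yolk sac edema
  AXIS:   {weight: 1.0, group: 120hpf}  # body axis defect
  EYE:    {weight: 1.0, group: 120hpf}  # eye malformation
  SNOUT:  {weight: 1.0, group: 120hpf}  # snout malformation
  JAW:    {weight: 1.0, group: 120hpf}  # jaw malformation
  OTIC:   {weight: 1.0, group: 120hpf}  # otic vesicle defect
  PE:     {weight: 1.0, group: 120hpf}  # pericardial edema
  BRAIN:  {weight: 1.0, group: 120hpf}  # brain malformation
  SOMITE: {weight: 1.0, group: 120hpf}  # somite defect
  PFIN:   {weight: 1.0, group: 120hpf}  # pectoral fin defect
  CFIN:   {weight: 1.0, group: 120hpf}  # caudal fin defect
  PIG:    {weight: 1.0, group: 120hpf}  # pigmentation defect
  CIRC:   {weight: 1.0, group: 120hpf}  # circulation defect
  TRUNK:  {weight: 1.0, group: 120hpf}  # trunk malformation
  SWIM:   {weight: 1.0, group: 120hpf}  # swim bladder not inflated
  NC:     {weight: 1.0, group: 120hpf}  # notochord malformation, 120 hpf
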