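# Section policy: heading patterns (case-insensitive, matched at line start,
# optionally followed by ":") and the per-category scope decision.
# Out-of-scope sections are excluded as tumor-mass / tumor-size candidate
# sources; involvement and presence concepts still pass through the normal
# context rules wherever they occur.
default_in_scope: true
categories:
  history:
    in_scope: false
    patterns: ["clinical history", "history", "indication", "clinical indication"]
  comparison:
    in_scope: false
    patterns: ["comparison", "comparisons"]
  technique:
    in_scope: false
    patterns: ["technique", "procedure", "protocol"]
  findings:
    in_scope: true
    patterns: ["findings pet[- ]?ct", "pet[- ]?ct findings", "findings pet", "pet findings",
               "findings ct", "ct findings", "findings", "impression"]
  head:
    in_scope: false
    patterns: ["head", "brain"]
  neck:
    in_scope: false
    patterns: ["neck"]
  chest:
    in_scope: true
    patterns: ["chest", "thorax", "lungs", "chest/thorax"]
  mediastinum:
    in_scope: true
    patterns: ["mediastinum and hila", "mediastinum", "hila"]
  abdomen:
    in_scope: false
    patterns: ["abdomen and pelvis", "abdomen/pelvis", "abdomen"]
  pelvis:
    in_scope: false
    patterns: ["pelvis"]
  bones:
    in_scope: false
    patterns: ["bones", "osseous structures", "skeleton"]
  musculoskeletal:
    in_scope: false
    patterns: ["musculoskeletal", "soft tissues", "msk"]
  other:
    in_scope: true
    patterns: []
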