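# T-substage decision table, AJCC/TNM 8th edition descriptors for lung.
# Size classes are "> lower, <= upper" in millimetres; a size above the last
# breakpoint is T4. Involvement structures map to the minimum tier implied by
# direct invasion. Presence findings map to fixed tiers; a nodule in a
# different ipsilateral lobe only counts when larger than nodule_min_size_mm.
version: AJCC8
size_breakpoints_mm:
  T1a: 10
  T1b: 20
  T1c: 30
  T2a: 40
  T2b: 50
  T3: 70
involvement_tiers:
  T2: [main_bronchus, visceral_pleura]
  T3: [chest_wall, parietal_pericardium, phrenic_nerve]
  T4: [mediastinum, diaphragm, heart, great_vessels, trachea, carina,
       esophagus, recurrent_laryngeal_nerve, vertebral_body]
presence_map:
  post_obstructive_atelectasis: T2
  main_bronchus: T2
  satellite_same_lobe: T3
  nodule_ipsilateral_other_lobe: T4
nodule_min_size_mm: 10
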