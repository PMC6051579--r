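# Reference character profiles for the 13 laccate Ganoderma taxa of the
# United States (plus Tomophagus colossus), one profile per taxon.
# Missing / inapplicable states are encoded as YAML null, never "".
# pores are pores/mm intervals; spore dimensions are per-taxon means in um.
"G. curtisii":
  context_color: buff
  melanoid_deposits: present
  concentric_zones: absent
  contextual_chlamydospores: absent
  culture_chlamydospores: absent
  stipe_class: stipitate
  pores_min: 5
  pores_max: 8
  host_group: hardwood
  region: eastern_US
  growth_rate_class: fast
  spore_length_mean: 10.6
  spore_width_mean: 6.4
  pileus_notes: "laterally stipitate; pileus yellow-orange to reddish brown, often with purple hues"
"G. curtisii f.sp. meredithiae":
  context_color: buff
  melanoid_deposits: present
  concentric_zones: absent
  contextual_chlamydospores: absent
  culture_chlamydospores: absent
  stipe_class: stipitate
  pores_min: 5
  pores_max: 8
  host_group: conifer
  region: eastern_US
  growth_rate_class: slow
  spore_length_mean: 10.8
  spore_width_mean: 6.8
  pileus_notes: "on pines in the southeastern US; slow dikaryotic growth on malt extract agar"
"G. lucidum":
  context_color: buff
  melanoid_deposits: absent
  concentric_zones: present
  contextual_chlamydospores: absent
  culture_chlamydospores: absent
  stipe_class: stipitate
  pores_min: 4
  pores_max: 5
  host_group: hardwood
  region: restricted_UT_CA
  growth_rate_class: null
  spore_length_mean: 10.7
  spore_width_mean: 7.1
  pileus_notes: "isolated introduced populations in anthropogenic habitats"
"G. martinicense":
  context_color: dark_brown
  melanoid_deposits: present
  concentric_zones: present
  contextual_chlamydospores: absent
  culture_chlamydospores: present
  stipe_class: pseudostipitate
  pores_min: 5
  pores_max: 6
  host_group: hardwood
  region: eastern_US
  growth_rate_class: null
  spore_length_mean: 11.1
  spore_width_mean: 6.9
  pileus_notes: "central pseudostipe, dark red to black"
"G. oregonense":
  context_color: white
  melanoid_deposits: absent
  concentric_zones: absent
  contextual_chlamydospores: absent
  culture_chlamydospores: absent
  stipe_class: pseudostipitate
  pores_min: 3
  pores_max: 4
  host_group: conifer
  region: pacific_northwest
  growth_rate_class: null
  spore_length_mean: 12.9
  spore_width_mean: 8.0
  pileus_notes: null
"G. polychromum":
  context_color: buff
  melanoid_deposits: absent
  concentric_zones: present
  contextual_chlamydospores: absent
  culture_chlamydospores: present
  stipe_class: sessile
  pores_min: 4
  pores_max: 5
  host_group: hardwood
  region: western_US
  growth_rate_class: null
  spore_length_mean: 12.2
  spore_width_mean: 6.8
  pileus_notes: "conspicuous concentric growth zones in the context"
"G. ravenelii":
  context_color: buff
  melanoid_deposits: absent
  concentric_zones: absent
  contextual_chlamydospores: absent
  culture_chlamydospores: absent
  stipe_class: stipitate
  pores_min: 6
  pores_max: 7
  host_group: hardwood
  region: eastern_US
  growth_rate_class: null
  spore_length_mean: 11.2
  spore_width_mean: 5.2
  pileus_notes: "elongated elliptical basidiospores"
"G. sessile":
  context_color: buff
  melanoid_deposits: absent
  concentric_zones: present
  contextual_chlamydospores: absent
  culture_chlamydospores: present
  stipe_class: sessile
  pores_min: 5
  pores_max: 7
  host_group: hardwood
  region: eastern_US
  growth_rate_class: null
  spore_length_mean: 11.4
  spore_width_mean: 6.6
  pileus_notes: "deep red to orangish-red pileus; widely distributed east of the Rockies"
"G. tsugae":
  context_color: white
  melanoid_deposits: absent
  concentric_zones: absent
  contextual_chlamydospores: absent
  culture_chlamydospores: absent
  stipe_class: pseudostipitate
  pores_min: 5
  pores_max: 7
  host_group: conifer
  region: eastern_US
  growth_rate_class: null
  spore_length_mean: 9.9
  spore_width_mean: 6.5
  pileus_notes: "on Tsuga canadensis in boreal hemlock forests"
"G. tuberculosum":
  context_color: dark_brown
  melanoid_deposits: present
  concentric_zones: present
  contextual_chlamydospores: absent
  culture_chlamydospores: absent
  stipe_class: sessile
  pores_min: 4
  pores_max: 7
  host_group: hardwood
  region: subtropical
  growth_rate_class: null
  spore_length_mean: 10.5
  spore_width_mean: 7.3
  pileus_notes: "orange to red when active, dark red when mature; resinous deposits lighter than the context"
"G. cf. weberianum":
  context_color: buff
  melanoid_deposits: absent
  concentric_zones: present
  contextual_chlamydospores: present
  culture_chlamydospores: present
  stipe_class: sessile
  pores_min: 5
  pores_max: 7
  host_group: hardwood
  region: subtropical
  growth_rate_class: null
  spore_length_mean: 8.4
  spore_width_mean: 5.6
  pileus_notes: "pigmented striate contextual chlamydospores; subtropical south Florida"
"G. zonatum":
  context_color: dark_brown
  melanoid_deposits: absent
  concentric_zones: present
  contextual_chlamydospores: absent
  culture_chlamydospores: absent
  stipe_class: sessile
  pores_min: 4
  pores_max: 6
  host_group: monocot
  region: eastern_US
  growth_rate_class: null
  spore_length_mean: 11.8
  spore_width_mean: 5.9
  pileus_notes: "on palms and other monocots"
"T. colossus":
  context_color: white
  melanoid_deposits: absent
  concentric_zones: absent
  contextual_chlamydospores: present
  culture_chlamydospores: present
  stipe_class: sessile
  pores_min: 3
  pores_max: 4
  host_group: cycad
  region: subtropical
  growth_rate_class: null
  spore_length_mean: 16.1
  spore_width_mean: 10.4
  pileus_notes: "spongy, light-weight, shiny mustard-yellow fruiting body"
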