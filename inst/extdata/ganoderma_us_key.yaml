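# Dichotomous key to the laccate Ganoderma of the United States, encoded as
# data. Twelve couplets, two leads each; a lead either forwards to another
# couplet (goto) or terminates at a taxon (species). Predicates are
# conjunctions over CharacterProfile fields. Spore-size ranges are printed
# per-taxon min-max ranges with closed endpoints; `ambiguous_values` lists
# profile states that make a predicate undecidable (both leads followed).
couplets:
  - id: 1
    leads:
      - predicates:
          - {character: context_color, op: eq, value: white}
        goto: 2
      - predicates:
          - {character: context_color, op: neq, value: white}
        goto: 4
  - id: 2
    leads:
      - predicates:
          - {character: spore_length_mean, op: range, min: 14.6, max: 17.3}
          - {character: spore_width_mean, op: range, min: 9.5, max: 11.3}
        species: "T. colossus"
      - predicates:
          - {character: spore_length_mean, op: lt, value: 14.6}
        goto: 3
  - id: 3
    leads:
      - predicates:
          - {character: host_group, op: eq, value: conifer}
          - {character: region, op: eq, value: pacific_northwest}
          - {character: spore_length_mean, op: range, min: 11.6, max: 14.9}
          - {character: spore_width_mean, op: range, min: 6.7, max: 9.3}
        species: "G. oregonense"
      - predicates:
          - {character: host_group, op: eq, value: conifer}
          - {character: region, op: eq, value: eastern_US}
          - {character: spore_length_mean, op: range, min: 8.9, max: 11.5}
          - {character: spore_width_mean, op: range, min: 5.2, max: 7.7}
        species: "G. tsugae"
  - id: 4
    leads:
      - predicates:
          - {character: context_color, op: eq, value: buff}
        goto: 5
      - predicates:
          - {character: context_color, op: eq, value: dark_brown}
        goto: 11
  - id: 5
    leads:
      - predicates:
          - {character: melanoid_deposits, op: eq, value: present}
        goto: 6
      - predicates:
          - {character: melanoid_deposits, op: eq, value: absent}
        goto: 7
  - id: 6
    leads:
      - predicates:
          - {character: host_group, op: eq, value: hardwood}
          - {character: growth_rate_class, op: eq, value: fast}
        species: "G. curtisii"
      - predicates:
          - {character: host_group, op: eq, value: conifer}
          - {character: growth_rate_class, op: eq, value: slow}
        species: "G. curtisii f.sp. meredithiae"
  - id: 7
    leads:
      - predicates:
          - {character: stipe_class, op: in_set, values: [sessile, pseudostipitate]}
        goto: 8
      - predicates:
          - {character: stipe_class, op: eq, value: stipitate}
        goto: 10
  - id: 8
    leads:
      - predicates:
          - {character: region, op: eq, value: western_US}
        species: "G. polychromum"
      - predicates:
          - {character: region, op: neq, value: western_US}
        goto: 9
  - id: 9
    leads:
      - predicates:
          - {character: contextual_chlamydospores, op: eq, value: present}
          - {character: region, op: eq, value: subtropical}
        species: "G. cf. weberianum"
      - predicates:
          - {character: host_group, op: eq, value: hardwood}
          - {character: spore_length_mean, op: range, min: 9.7, max: 14.0}
          - {character: spore_width_mean, op: range, min: 5.2, max: 8.4}
        species: "G. sessile"
  - id: 10
    leads:
      - predicates:
          - {character: concentric_zones, op: eq, value: absent}
          - {character: spore_length_mean, op: range, min: 9.1, max: 13.6}
          - {character: spore_width_mean, op: range, min: 4.2, max: 6.8}
        species: "G. ravenelii"
      - predicates:
          - {character: concentric_zones, op: eq, value: present}
          - {character: region, op: eq, value: restricted_UT_CA,
             ambiguous_values: [western_US]}
        species: "G. lucidum"
  - id: 11
    leads:
      - predicates:
          - {character: host_group, op: eq, value: monocot}
          - {character: spore_length_mean, op: range, min: 10.3, max: 13.7}
          - {character: spore_width_mean, op: range, min: 5.0, max: 6.6}
        species: "G. zonatum"
      - predicates:
          - {character: host_group, op: neq, value: monocot}
        goto: 12
  - id: 12
    leads:
      - predicates:
          - {character: stipe_class, op: eq, value: pseudostipitate}
          - {character: melanoid_deposits, op: eq, value: present}
          - {character: host_group, op: eq, value: hardwood}
          - {character: pores_per_mm, op: overlap, min: 5, max: 6}
        species: "G. martinicense"
      - predicates:
          - {character: stipe_class, op: eq, value: sessile}
          - {character: region, op: eq, value: subtropical}
          - {character: spore_length_mean, op: range, min: 9.2, max: 12.0}
          - {character: spore_width_mean, op: range, min: 6.2, max: 8.6}
        species: "G. tuberculosum"
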