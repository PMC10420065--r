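# Pediatric Crohn's Disease Activity Index (PCDAI), Hyams et al. 1991.
# Point values follow the original publication. Levels without a `when`
# clause are declared for range validation but cannot be reached from
# the binary/categorical visit fields of this cohort schema (e.g.
# "severe" abdominal pain cannot be distinguished from "moderate" when
# pain is recorded yes/no); scoring then uses the reachable level.
# Hematocrit scoring in the original is sex- and age-dependent; a
# single representative band is encoded here (editable).
name: pcdai
label: Pediatric Crohn's Disease Activity Index
synthetic_weights: false
declared_range: [0, 100]
cutoffs:
  - category: remission
    upper: 10
    upper_inclusive: true
  - category: mild
    upper: 30
    upper_inclusive: true
  - category: moderate_severe
components:
  - name: abdominal_pain
    inputs: [abdominal_pain]
    levels:
      - points: 10        # severe pain / interfering with activities
      - points: 5
        when:
          - abdominal_pain: ["yes"]
      - points: 0
        when:
          - abdominal_pain: ["no"]
  - name: stools
    inputs: [stool_blood, stool_consistency, stool_quantity]
    levels:
      - points: 10        # gross bleeding with liquid stools
        when:
          - stool_blood: ["yes"]
            stool_consistency: ["semi_formed_liquid"]
      - points: 5
        when:
          - stool_blood: ["yes"]
          - stool_quantity: ["gt3"]
      - points: 0
        when:
          - {}
  - name: well_being
    inputs: [condition]
    levels:
      - points: 10        # very poor
      - points: 5
        when:
          - condition: ["reduced_poor"]
      - points: 0
        when:
          - condition: ["good"]
  - name: weight
    inputs: [weight_gain]
    levels:
      - points: 10        # weight loss >= 10%
      - points: 5
        when:
          - weight_gain: ["involuntary"]
      - points: 0
        when:
          - weight_gain: ["voluntary"]
  - name: height
    inputs: [height_gain]
    levels:
      - points: 10        # channel decrease > 2 channels
      - points: 5
        when:
          - height_gain: ["no"]
      - points: 0
        when:
          - height_gain: ["yes"]
  - name: abdomen
    inputs: [abdominal_finding, pressure_pain, resistance]
    levels:
      - points: 10        # tenderness, involuntary guarding, definite mass
        when:
          - resistance: ["yes"]
      - points: 5
        when:
          - abdominal_finding: ["with_findings"]
          - pressure_pain: ["yes"]
      - points: 0
        when:
          - {}
  - name: perirectal
    inputs: [anal_finding]
    levels:
      - points: 10        # active fistula, drainage, tenderness, abscess
      - points: 5
        when:
          - anal_finding: ["yes"]
      - points: 0
        when:
          - anal_finding: ["no"]
  - name: extraintestinal
    inputs: [extraintestinal]
    levels:
      - points: 10        # two or more manifestations
      - points: 5
        when:
          - extraintestinal: ["yes"]
      - points: 0
        when:
          - extraintestinal: ["no"]
  - name: hematocrit
    inputs: [hematocrit]
    levels:
      - points: 0
        when:
          - hematocrit: {min: 0.33, min_inclusive: true}
      - points: 2.5
        when:
          - hematocrit: {min: 0.28, max: 0.33, min_inclusive: true, max_inclusive: false}
      - points: 5
        when:
          - hematocrit: {max: 0.28, max_inclusive: false}
  - name: esr
    inputs: [esr]
    levels:
      - points: 0
        when:
          - esr: {max: 20, max_inclusive: false}
      - points: 2.5
        when:
          - esr: {min: 20, max: 50, min_inclusive: true, max_inclusive: true}
      - points: 5
        when:
          - esr: {min: 50, min_inclusive: false}
  - name: albumin
    inputs: [albumin]
    levels:
      - points: 0
        when:
          - albumin: {min: 35, min_inclusive: true}
      - points: 5
        when:
          - albumin: {min: 31, max: 35, min_inclusive: true, max_inclusive: false}
      - points: 10
        when:
          - albumin: {max: 31, max_inclusive: false}
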