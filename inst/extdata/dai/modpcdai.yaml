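# Modified PCDAI (modPCDAI), 2010: the full PCDAI item set extended by
# a C-reactive protein component. SYNTHETIC WEIGHTS: the per-level CRP
# point values were not available when this table was transcribed;
# the CRP levels {0, 7.5, 15} are chosen to reproduce the published
# total range 0-115 and are validated by brute force. Edit against the
# primary reference before clinical use.
name: modpcdai
label: Modified PCDAI
synthetic_weights: true
declared_range: [0, 115]
cutoffs:
  - category: remission
    upper: 7.5
    upper_inclusive: false
  - category: mild
    upper: 12.5
    upper_inclusive: false
  - category: moderate_severe
    upper: 17.5
    upper_inclusive: true
  - category: severe
components:
  - name: abdominal_pain
    inputs: [abdominal_pain]
    levels:
      - points: 10
      - points: 5
        when:
          - abdominal_pain: ["yes"]
      - points: 0
        when:
          - abdominal_pain: ["no"]
  - name: stools
    inputs: [stool_blood, stool_consistency, stool_quantity]
    levels:
      - points: 10
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
      - points: 10
      - points: 5
        when:
          - condition: ["reduced_poor"]
      - points: 0
        when:
          - condition: ["good"]
  - name: weight
    inputs: [weight_gain]
    levels:
      - points: 10
      - points: 5
        when:
          - weight_gain: ["involuntary"]
      - points: 0
        when:
          - weight_gain: ["voluntary"]
  - name: height
    inputs: [height_gain]
    levels:
      - points: 10
      - points: 5
        when:
          - height_gain: ["no"]
      - points: 0
        when:
          - height_gain: ["yes"]
  - name: abdomen
    inputs: [abdominal_finding, pressure_pain, resistance]
    levels:
      - points: 10
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
      - points: 10
      - points: 5
        when:
          - anal_finding: ["yes"]
      - points: 0
        when:
          - anal_finding: ["no"]
  - name: extraintestinal
    inputs: [extraintestinal]
    levels:
      - points: 10
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
  - name: crp
    inputs: [crp]
    levels:
      - points: 0
        when:
          - crp: {max: 5, max_inclusive: false}
      - points: 7.5
        when:
          - crp: {min: 5, max: 25, min_inclusive: true, max_inclusive: false}
      - points: 15
        when:
          - crp: {min: 25, min_inclusive: true}
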