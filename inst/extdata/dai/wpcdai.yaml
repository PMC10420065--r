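# Weighted PCDAI (wPCDAI), Turner et al. 2011. Point values follow the
# original publication: general well-being and abdominal pain weighted
# to 20, stools/ESR/perirectal to 15, albumin to 20, weight to 10,
# extra-intestinal manifestations 0/10. Total range 0-125.
name: wpcdai
label: Weighted PCDAI
synthetic_weights: false
declared_range: [0, 125]
cutoffs:
  - category: remission
    upper: 12.5
    upper_inclusive: false
  - category: mild
    upper: 40
    upper_inclusive: true
  - category: moderate_severe
    upper: 57.5
    upper_inclusive: true
  - category: severe
components:
  - name: well_being
    inputs: [condition]
    levels:
      - points: 20
      - points: 10
        when:
          - condition: ["reduced_poor"]
      - points: 0
        when:
          - condition: ["good"]
  - name: abdominal_pain
    inputs: [abdominal_pain]
    levels:
      - points: 20
      - points: 10
        when:
          - abdominal_pain: ["yes"]
      - points: 0
        when:
          - abdominal_pain: ["no"]
  - name: stools
    inputs: [stool_blood, stool_consistency, stool_quantity]
    levels:
      - points: 15
        when:
          - stool_blood: ["yes"]
            stool_consistency: ["semi_formed_liquid"]
      - points: 7.5
        when:
          - stool_blood: ["yes"]
          - stool_quantity: ["gt3"]
      - points: 0
        when:
          - {}
  - name: esr
    inputs: [esr]
    levels:
      - points: 0
        when:
          - esr: {max: 20, max_inclusive: false}
      - points: 7.5
        when:
          - esr: {min: 20, max: 50, min_inclusive: true, max_inclusive: true}
      - points: 15
        when:
          - esr: {min: 50, min_inclusive: false}
  - name: albumin
    inputs: [albumin]
    levels:
      - points: 0
        when:
          - albumin: {min: 35, min_inclusive: true}
      - points: 10
        when:
          - albumin: {min: 31, max: 35, min_inclusive: true, max_inclusive: false}
      - points: 20
        when:
          - albumin: {max: 31, max_inclusive: false}
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
  - name: perirectal
    inputs: [anal_finding]
    levels:
      - points: 15
      - points: 7.5
        when:
          - anal_finding: ["yes"]
      - points: 0
        when:
          - anal_finding: ["no"]
  - name: extraintestinal
    inputs: [extraintestinal]
    levels:
      - points: 10
        when:
          - extraintestinal: ["yes"]
      - points: 0
        when:
          - extraintestinal: ["no"]
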