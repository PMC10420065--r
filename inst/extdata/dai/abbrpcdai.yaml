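# Abbreviated PCDAI (abbrPCDAI), Shepanski et al. 2004: the PCDAI
# history/examination items without the laboratory block or height.
# No validated total range or severity cut-offs have been published
# for this index, so only the score is computed here and range
# validation is skipped.
name: abbrpcdai
label: Abbreviated PCDAI
synthetic_weights: true
declared_range: null
cutoffs: []
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
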