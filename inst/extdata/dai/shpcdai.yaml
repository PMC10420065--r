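# Short PCDAI (shPCDAI), Kappelman et al. 2011: six history and
# examination items, no laboratory block. SYNTHETIC WEIGHTS: the
# re-weighted per-level point values were not available when this
# table was transcribed; uniform levels {0, 7.5, 15} are chosen to
# reproduce the published total range 0-90 and are validated by brute
# force. Edit against the primary reference before clinical use.
name: shpcdai
label: Short PCDAI
synthetic_weights: true
declared_range: [0, 90]
cutoffs:
  - category: remission
    upper: 15
    upper_inclusive: false
  - category: mild
    upper: 30
    upper_inclusive: false
  - category: moderate_severe
components:
  - name: abdominal_pain
    inputs: [abdominal_pain]
    levels:
      - points: 15
      - points: 7.5
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
  - name: well_being
    inputs: [condition]
    levels:
      - points: 15
      - points: 7.5
        when:
          - condition: ["reduced_poor"]
      - points: 0
        when:
          - condition: ["good"]
  - name: weight
    inputs: [weight_gain]
    levels:
      - points: 15
      - points: 7.5
        when:
          - weight_gain: ["involuntary"]
      - points: 0
        when:
          - weight_gain: ["voluntary"]
  - name: abdomen
    inputs: [abdominal_finding, pressure_pain, resistance]
    levels:
      - points: 15
        when:
          - resistance: ["yes"]
      - points: 7.5
        when:
          - abdominal_finding: ["with_findings"]
          - pressure_pain: ["yes"]
      - points: 0
        when:
          - {}
  - name: extraintestinal
    inputs: [extraintestinal]
    levels:
      - points: 15
      - points: 7.5
        when:
          - extraintestinal: ["yes"]
      - points: 0
        when:
          - extraintestinal: ["no"]
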