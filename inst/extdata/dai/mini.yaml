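# Mucosal Inflammation Noninvasive Index (MINI), 2019: fecal
# calprotectin, stool frequency, and C-reactive protein and/or
# erythrocyte sedimentation rate (either marker may be used; using both
# is preferred — encoded as the substitution group
# "inflammatory_marker", whose members are skipped individually when
# missing as long as one is present). SYNTHETIC WEIGHTS: the per-level
# point values were not available when this table was transcribed;
# the levels are chosen to reproduce the published total range -3 to 25
# (fecal calprotectin below 100 mg/kg scores negative) and are
# validated by brute force. Edit against the primary reference before
# clinical use.
name: mini
label: Mucosal Inflammation Noninvasive Index
synthetic_weights: true
declared_range: [-3, 25]
cutoffs:
  - category: remission
    upper: 8
    upper_inclusive: false
  - category: mild
    upper: 11
    upper_inclusive: true
  - category: moderate_severe
components:
  - name: fecal_calprotectin
    inputs: [fc]
    levels:
      - points: -3
        when:
          - fc: {max: 100, max_inclusive: false}
      - points: 0
        when:
          - fc: {min: 100, max: 600, min_inclusive: true, max_inclusive: false}
      - points: 4
        when:
          - fc: {min: 600, max: 1200, min_inclusive: true, max_inclusive: false}
      - points: 8
        when:
          - fc: {min: 1200, min_inclusive: true}
  - name: stools
    inputs: [stool_quantity]
    levels:
      - points: 10        # more than 8 stools per 24 h
      - points: 5
        when:
          - stool_quantity: ["gt3"]
      - points: 0
        when:
          - stool_quantity: ["le3"]
  - name: crp
    inputs: [crp]
    substitution_group: inflammatory_marker
    levels:
      - points: 0
        when:
          - crp: {max: 5, max_inclusive: false}
      - points: 2.5
        when:
          - crp: {min: 5, max: 25, min_inclusive: true, max_inclusive: false}
      - points: 5
        when:
          - crp: {min: 25, min_inclusive: true}
  - name: esr
    inputs: [esr]
    substitution_group: inflammatory_marker
    levels:
      - points: 0
        when:
          - esr: {max: 20, max_inclusive: false}
      - points: 1
        when:
          - esr: {min: 20, max: 50, min_inclusive: true, max_inclusive: true}
      - points: 2
        when:
          - esr: {min: 50, min_inclusive: false}
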