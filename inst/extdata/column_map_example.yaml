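# Example column mapping for readCohort(): canonical name -> file header.
# Edit the right-hand side to match your table's headers.
eye_id: ID
amplitude_rater1: Amp_R1
amplitude_rater1_repeat: Amp_R1_repeat
amplitude_rater2: Amp_R2
ovality_ratio: Ovality
spherical_equivalent: SE_diopters
axial_length: AL_mm
body_height: Height_cm
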