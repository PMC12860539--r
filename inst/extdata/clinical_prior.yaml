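# Literature-based tissue-stiffness prior for a transperineal prostate
# insertion path (muscle -> prostate -> muscle). Means: prostate 0.043 MPa
# (average of published benign 0.0175 MPa and cancerous 0.070 MPa moduli,
# averaged to stay unbiased with respect to cancer state); pelvic muscle
# 0.0103 MPa (gastrocnemius tangent modulus at zero compression, averaged
# over fiber orientations). A wide sigma of 0.08 MPa reflects the spread
# of reported measurements. Layer boundaries are placeholders: the true
# geometry comes from patient imaging, which this package does not ingest.
prior:
  mu: [0.0103, 0.043, 0.0103]
  sigma: [0.08, 0.08, 0.08]
  boundaries: [40, 80]
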