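# Reference classification configuration: published per-marker intensity
# thresholds for islet / SC-islet / bladder quantification. Channel indices
# assume channel 1 = nuclear counterstain (DAPI), channel 2 = green
# (C-peptide / insulin / CK05), channel 3 = red (glucagon). Enable the
# entries matching your staining; "high" entries reuse a channel with a
# stricter cutoff to isolate high-expressing subpopulations.
channels:
- channel: 2
  name: C-peptide (SC-islets)
  threshold: 40.0
  enabled: yes
- channel: 3
  name: Glucagon (SC-islets)
  threshold: 50.0
  enabled: yes
- channel: 2
  name: High C-peptide (SC-islets)
  threshold: 150.0
  enabled: no
- channel: 3
  name: High glucagon (SC-islets)
  threshold: 150.0
  enabled: no
- channel: 2
  name: Insulin (mouse-islets)
  threshold: 150.0
  enabled: no
- channel: 3
  name: Glucagon (mouse-islets)
  threshold: 30.0
  enabled: no
- channel: 2
  name: CK05
  threshold: 30.0
  enabled: no
intensity_method: ring
expansion:
  distance_um: 1.0
  mode: independent
segmentation:
  backend: classical
  smooth_sigma_um: 0.25
  min_area_um2: 4.0
nuclear_channel: 1
projection: max
note: >
  Reference thresholds derived as 0.6 x a manually measured representative
  intensity for each cell type.
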