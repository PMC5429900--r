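# Example plaquemorph run configuration. Every analysis parameter is
# exposed by name; omitted keys fall back to the package defaults shown.
inputs:
  - sections/proximal-001.png
  - sections/distal-001.png
group_labels:
  - proximal
  - distal
calibration:
  microns_per_pixel: 0.5
output_dir: results
seed: 1
write_overlays: true
color:
  # WHITE: bright and unsaturated, decided before the hue classes
  white_min_value: 0.85
  white_max_saturation: 0.15
  # pixels below these chroma gates (and not WHITE) become OTHER
  min_saturation: 0.15
  min_value: 0.15
  # hue sectors in degrees; low > high wraps through 0
  hue_ranges:
    ERYTHROCYTE_YELLOW: [40, 70]
    COLLAGEN_BLUE: [190, 260]
    ELASTIC_PURPLE: [260, 320]
    RED_PINK: [320, 40]
  # prototype 8-bit RGB per class (synthetic rendering, sanity checks)
  prototypes:
    ELASTIC_PURPLE: [150, 60, 170]
    COLLAGEN_BLUE: [40, 70, 200]
    ERYTHROCYTE_YELLOW: [230, 200, 30]
    RED_PINK: [230, 120, 140]
    WHITE: [255, 255, 255]
segmentation:
  # smallest filled interior accepted as a lamina ring (pixels)
  min_enclosed_area: 500
  # disc radius for morphological ring closure (bridges broken laminae)
  closing_radius: 3
  # maximum mean ring thickness (pixels)
  max_thickness: 15
  # erythrocyte pixels required to call a white region lumen
  # (10 px at 0.5 um/px; scales with the inverse square of calibration)
  min_rbc_pixels: 10
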