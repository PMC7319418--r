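# Foraging-suitability reclassification tables (0 unsuitable .. 5 preferred).
# One entry per landcover source. "categorical" sources map class labels to
# values; "percent" sources map tree-cover-density bands [low, high, value]
# (values outside every band become nodata).
- source_id: os_vector
  type: categorical
  classes:
    Boulders: 0
    Sand: 0
    Shingle: 0
    Building: 0
    Water: 0
    Heathland: 1
    Unimproved grass: 1
    Marsh: 1
    Reeds: 2
    Shrub and heathland: 2
    Coniferous woodland: 3
    Shrub and marsh: 3
    Shrub and unimproved: 3
    Broad-leafed woodland: 5
    Shrub: 5
    Mixed woodland: 5
    Orchard: 5
- source_id: lcm_raster
  type: categorical
  classes:
    Water: 0
    Rock: 0
    Saltmarsh: 0
    Urban: 0
    Suburban: 0
    Acid grassland: 1
    Calcareous grassland: 1
    Heather: 1
    Improved grassland: 1
    Bog: 1
    Arable and horticulture: 2
    Neutral grassland: 2
    Coniferous woodland: 3
    Broadleaf woodland: 5
- source_id: tcd_percent
  type: percent
  bands:
    - [1, 3, 1]
    - [4, 10, 2]
    - [11, 50, 3]
    - [51, 100, 4]
- source_id: wlff_lines
  type: categorical
  classes:
    Woody linear feature: 4
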