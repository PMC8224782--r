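# Adult reference human physiology (male, ~73 kg).
# Organ volumes and regional blood flows assembled from standard published
# reference compilations (ICRP Publication 89 reference anatomy; regional
# perfusion values as tabulated in the whole-body PBPK literature, e.g.
# Willmann et al. 2003, Jones & Rowland-Yeo 2013). The liver row's flow is the
# HEPATIC ARTERIAL flow; portal venous inflow to the liver is the sum of the
# flows of the organs with drains: portal. Cardiac output is the sum of all
# systemic organ flows (~300 L/h at rest).
species: human
hematocrit: 0.47
venous_volume_l: 2.6
arterial_volume_l: 1.5
plasma_protein_scale: 1.0
# CYP3A4 tissue concentrations (umol enzyme / L tissue). Not printed in the
# source drug profile; documented literature defaults (hepatic microsomal
# abundance scaled to whole liver; total small-intestinal CYP3A4 ~70 nmol
# over ~1.1 L mucosa). Tunable.
cyp3a4:
  liver: 4.32
  gut_wall: 0.07
organs:
  - {name: lung,        volume_l: 0.50,  flow_l_h: 299.0, drains: arterial}
  - {name: adipose,     volume_l: 14.0,  flow_l_h: 18.7,  drains: venous}
  - {name: bone,        volume_l: 10.2,  flow_l_h: 18.2,  drains: venous}
  - {name: brain,       volume_l: 1.45,  flow_l_h: 43.2,  drains: venous}
  - {name: heart,       volume_l: 0.33,  flow_l_h: 14.4,  drains: venous}
  - {name: kidney,      volume_l: 0.31,  flow_l_h: 66.0,  drains: venous}
  - {name: muscle,      volume_l: 29.0,  flow_l_h: 45.0,  drains: venous}
  - {name: skin,        volume_l: 3.30,  flow_l_h: 11.3,  drains: venous}
  - {name: rest,        volume_l: 3.00,  flow_l_h: 9.0,   drains: venous}
  - {name: gut_wall,    volume_l: 1.10,  flow_l_h: 38.0,  drains: portal}
  - {name: spleen,      volume_l: 0.15,  flow_l_h: 4.6,   drains: portal}
  - {name: pancreas,    volume_l: 0.10,  flow_l_h: 3.6,   drains: portal}
  - {name: stomach,     volume_l: 0.15,  flow_l_h: 3.6,   drains: portal}
  - {name: liver,       volume_l: 1.80,  flow_l_h: 23.4,  drains: venous}
# Fasted-state GI segments. Lumen volumes and pH from standard fasted human
# values; effective absorptive areas include villous/microvillous surface
# amplification of the mucosa (total small-intestinal effective area
# ~4.5e5 cm2); the stomach is treated as non-absorbing for a lipophilic base.
gi:
  - {name: stomach,       volume_l: 0.050, area_cm2: 0.0,      ph: 2.0, transit_h: 0.25}
  - {name: duodenum,      volume_l: 0.040, area_cm2: 44000.0,  ph: 6.0, transit_h: 0.20}
  - {name: jejunum_upper, volume_l: 0.150, area_cm2: 160000.0, ph: 6.2, transit_h: 0.75}
  - {name: jejunum_lower, volume_l: 0.120, area_cm2: 130000.0, ph: 6.4, transit_h: 0.75}
  - {name: ileum_upper,   volume_l: 0.100, area_cm2: 90000.0,  ph: 6.8, transit_h: 0.80}
  - {name: ileum_lower,   volume_l: 0.080, area_cm2: 70000.0,  ph: 7.2, transit_h: 0.80}
  - {name: caecum,        volume_l: 0.050, area_cm2: 5000.0,   ph: 6.0, transit_h: 4.0}
  - {name: colon,         volume_l: 0.200, area_cm2: 20000.0,  ph: 6.5, transit_h: 13.0}
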