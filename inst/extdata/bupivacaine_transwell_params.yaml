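# Bupivacaine liposome-alginate depot in a 24-well transwell system.
# All quantities SI with explicit unit strings; concentrations in mM
# (numerically mol/m^3). Geometry is catalog-typical for 24-well inserts:
# 0.33 cm^2 membrane, 1.9 cm^2 well, 100 uL insert / 600 uL well fluid.
geometry:
  plate_format: well24
  insert_membrane_area: {value: 3.3e-5, unit: "m^2"}
  insert_fluid_depth: {value: 3.030303e-3, unit: "m"}
  well_cross_area: {value: 1.9e-4, unit: "m^2"}
  well_fluid_depth: {value: 3.157895e-3, unit: "m"}
  depot_thickness: {value: 3.030303e-3, unit: "m"}
drug:
  name: bupivacaine
  diffusivity_media: {value: 1.0e-10, unit: "m^2/s"}
  molar_mass: {value: 288.4, unit: "g/mol"}
construct:
  form: liposome_alginate
  initial_concentration: {value: 1.0, unit: "mM"}
  effective_diffusivity: {value: 8.5e-15, unit: "m^2/s"}
config:
  dt: {value: 10, unit: "s"}
  output_times: {value: [0, 1, 2, 4, 12, 24, 48, 96], unit: "h"}
  nodes_depot: 20
  nodes_media: 40
  scheme: backward_euler
metadata:
  # verbatim strings from the source report; the printed "mol/m^3" cannot be
  # a diffusivity unit and both values are interpreted as m^2/s
  diffusivity_media_printed_as: "1E-10 mol/m^3"
  effective_diffusivity_printed_as: "8.5E-15 mol/m^3"
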