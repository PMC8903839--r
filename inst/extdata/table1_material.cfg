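# Cartilage-mimetic pHEMA hydrogel material set (package preset, SI units)
# Load with read_material_config(); any key overrides the preset value.
preset = table1
# E_eq = 500e3          # Pa
# nu = 0.23
# porosity = 0.68
# permeability = 2.1e-14  # m^2
# Q_dis = 9000          # W/m^3
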