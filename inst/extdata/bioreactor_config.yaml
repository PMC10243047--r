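# 100-ml unbaffled stirred-tank bioreactor with a flat-blade paddle impeller;
# culture medium approximated by water. K_l a values are measured inputs.
vessel_diameter_m: 0.065
impeller_diameter_m: 0.0325
blade_height_m: 0.0039
liquid_height_m: 0.0299
working_volume_m3: 1.0e-4
density_kg_m3: 1000
kinematic_viscosity_m2_s: 1.0e-6
rpm: [50, 100]
kla_per_h: [0.89, 3.63]
shear_threshold_pa: 0.092
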