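name,density_g_cm3,effective_z,effective_a_g_mol,mean_excitation_energy_ev,radiation_length_g_cm2,electron_energy_cutoff_kev,photon_energy_cutoff_kev
water,1.000,7.42,13.37,75.0,36.08,25,10
pmma,1.190,6.47,12.00,74.0,40.55,25,10
air,0.0012048,7.64,15.31,85.7,36.62,25,10
aluminum,2.699,13.0,26.98,166.0,24.01,25,10
titanium,4.540,22.0,47.87,233.0,16.16,25,10
lead,11.35,82.0,207.2,823.0,6.37,12,10
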