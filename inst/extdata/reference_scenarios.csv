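parent_diameter_mm,mcr_pct,pore_density_per_mm2,energy_loss_baseline,energy_loss_stented,energy_loss_rr_pct,energy_loss_consistent,avg_velocity_baseline,avg_velocity_stented,avg_velocity_rr_pct,avg_velocity_consistent,inflow_baseline,inflow_stented,inflow_rr_pct,inflow_consistent
3.0,25.5,28.5,5235,2566,50.99,FALSE,0.0219,0.00923,57.81,FALSE,473.4,202.4,57.25,TRUE
3.5,29.4,31.9,855.8,409.2,52.19,TRUE,0.0169,0.00330,80.46,FALSE,285.7,81.98,71.30,FALSE
4.0,37.2,45.5,517.9,228.0,55.98,TRUE,0.0116,0.00192,83.43,FALSE,232.9,54.82,76.46,TRUE
4.5,48.0,73.5,313.5,137.6,56.12,FALSE,0.00859,0.00137,84.01,FALSE,167.1,38.40,77.02,TRUE
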