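fixture,quantity,inputs,expected
halflife,decomposition_flux,"D_M=100, k=ln2, t=1",50
slow_decay,decomposition_flux,"D_M=100, k=0.001, t=1",0.09995001666249781
q32,depth_m,"Q=32, c=0.2, f=0.4",0.8
q1,depth_m,"Q=1, c=0.2, f=0.4",0.2
small_catchment,depth_m,catchment=0.5 km2,0.05
circle_r1,perimeter_m,"area=pi, D_L=1",6.283185307179586
lake1e4_perimeter,perimeter_m,"area=1e4, D_L=1",354.4907701811032
lake1e4_shoreline,flow_per_m_shoreline,"flow=1, area=1e4, D_L=1",28.209479177387816
lake1e4_band10,flow_per_m2_recipient,"flow=1, area=1e4, D_L=1, band=10",2.8209479177387817
stream_w4,flow_per_m_shoreline,"flow=1, width=4",2
gsl_temperate,annual_flux,"1 per day, temperate",181
gsl_tropical,annual_flux,"1 per day, tropical",365
massloss_half,k_per_yr,"D_t/D_t0=0.5, t=1",0.6931471805599453
production_budget,k_per_yr,"D_P=100, E=20, D_F=40, t=1",0.6931471805599453
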