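column,type,unit,description
record_id,character,,unique identifier of the measurement
study_id,character,,identifier of the source study
ecosystem,enum,,recipient ecosystem type (see flux_vocab())
climate,enum,,climate zone of the site
flux_class,enum,,"kind of flux: gpp, ecosystem_respiration, nep, npp, secondary_production, detritus_stock, decomposition_rate, decomposition_flux, spatial_flow"
material_origin,enum,,material class of a spatial flow (none for local fluxes)
driver,enum,,transport driver of a spatial flow (none for local fluxes)
donor_ecosystem,enum,,donor ecosystem of a spatial flow (none for local fluxes)
value,double,raw unit,measured magnitude; negative allowed only for nep
mass_basis,enum,,"carbon, dry_weight, ash_free_dry_weight or wet_weight"
spatial_basis,enum,,"per_m2_recipient, per_m2_donor, per_m3, per_m_shoreline, per_lake or per_stream_reach"
time_basis,enum,,"per_year, per_day, per_study_period or none (stocks)"
study_period_days,double,d,length of the study period (per_study_period only)
carbon_fraction,double,gC/g,"carbon content reported by the study, overrides the conversion table"
lake_area_m2,double,m2,lake surface area
lake_volume_m3,double,m3,lake volume (mean depth = volume/area)
lake_perimeter_m,double,m,measured shoreline length; overrides the development-factor approximation
shoreline_development,double,,shoreline development factor D_L >= 1 (1 = circular)
stream_width_m,double,m,stream width
reach_length_m,double,m,stream reach length (per_stream_reach only)
discharge_m3s,double,m3/s,"river discharge, for the depth power law"
catchment_area_km2,double,km2,catchment area; < 1 km2 triggers the 5 cm depth rule
depth_m,double,m,measured mean depth for volumetric records
photic_depth_m,double,m,euphotic (e.g. Secchi) depth for pelagic volumetric records
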