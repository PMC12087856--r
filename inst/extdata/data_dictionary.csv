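column,type,unit,description
source_id,text,,free-text identifier of the source experiment
core_diameter,numeric,nm,nanoparticle core diameter (bare particle)
shape,enum sphere|rod|other,,particle shape; sphere is assumed when unreported
rod_length,numeric,nm,cylinder length; required for rods only
surface_area,numeric,nm^2,particle surface area; derived from diameter and shape when empty
volume,numeric,nm^3,particle volume; derived from diameter and shape when empty
sv_ratio,numeric,1/nm,surface-to-volume ratio; derived when empty
concentration,numeric,ug/mL,applied particle concentration; single declared unit per file
medium,enum aqueous|oil|emulsion|other,,qualitative medium class
np_class,enum inorganic|polymeric|other,,particle core material class
hydrophobicity_value,numeric,logKow or deg,outer-layer hydrophobicity on the scale named next
hydrophobicity_scale,enum logKow|contact_angle_deg,,logKow for organic particles; contact angle for inorganic
species,enum human|pig|rat|mouse|rabbit,,skin donor species
region,enum face|abdomen|arm|back|breast|ear|other,,body region of the specimen
sc_thickness,numeric,um,stratum corneum thickness
epidermis_thickness,numeric,um,viable epidermis thickness
dermis_thickness,numeric,um,dermis thickness
hf_density,numeric,1/cm^2,hair follicle density
hf_diameter,numeric,um,hair follicle opening diameter (plausibility band 5-500)
lipid_lipophilicity,numeric,,mass-weighted lipophilicity of SC lipids
lipid_polarity,numeric,,mass-weighted polarity of SC lipids
temperature,numeric,C,experimental temperature in [15 45]
contact_time,numeric,h,particle-skin contact time
in_vivo,boolean,,TRUE for in vivo; FALSE for ex vivo
depth,enum Surface|SC|Epidermis|Dermis|Distant,,layer where most particles accumulated
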