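# Reference substance panel: cefdinir and seven candidate stabilisers with
# literature Hansen components (MPa^0.5). printed_ra and printed_chi are the
# literature-reported interaction radius vs cefdinir and Flory-Huggins chi;
# they are carried for documentation and discrepancy reporting only and are
# never used as computation inputs (they are not reproducible from the delta
# components under the standard equations). Molar masses: monomeric
# substances from their molecular formulas (bundled IUPAC weights); polymers
# and silica have no single molar mass (NA).
name,role,delta_d,delta_p,delta_h,inorganic,molar_mass,formula,printed_ra,printed_chi
Cefdinir,drug,17.29,8.2,11.2,FALSE,395.41,C14H13N5O5S2,NA,NA
PVP K30,polymer,18.5,8.0,12.0,FALSE,NA,,4.11,0.098
HPMC 606,polymer,17.4,10.2,10.9,FALSE,NA,,3.93,0.076
Eudragit L100,polymer,17.6,9.5,6.9,FALSE,NA,,5.32,0.135
SBA-15,mesoporous_carrier,15.2,3.0,8.0,TRUE,NA,,7.92,NA
L-arginine,coformer,16.8,14.2,17.5,FALSE,174.20,C6H14N4O2,4.77,0.260
L-phenylalanine,coformer,18.3,8.4,11.2,FALSE,165.19,C9H11NO2,3.25,0.297
L-tryptophan,coformer,17.9,10.5,12.4,FALSE,204.23,C11H12N2O2,2.94,0.321
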