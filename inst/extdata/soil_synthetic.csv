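analyte,value,unit,basis,reference_date,source
Cs137,109,Bq/kg,dry,2013-07-01,literature wolf-range survey (2012-2014); reference_date assumed mid-survey
Cs137,141,Bq/kg,dry,2016-07-01,literature regional soil survey; reference_date assumed mid-survey
Pb210,42,Bq/kg,dry,2016-07-01,synthetic placeholder value
Ca,2400,mg/kg,dry,,synthetic placeholder value
Cd,1.1,mg/kg,dry,,synthetic placeholder value
Cu,32,mg/kg,dry,,synthetic placeholder value
Mn,900,mg/kg,dry,,synthetic placeholder value
Pb,65000,ug/kg,dry,,synthetic placeholder value (65 mg/kg)
Zn,95,mg/kg,dry,,synthetic placeholder value
Cs,4500,ug/kg,dry,,synthetic placeholder value (4.5 mg/kg)
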