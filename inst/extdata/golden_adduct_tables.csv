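source,mz,decomposition,polarity,confidence,note
Table 1,102,180 + Na+ + H+/2,positive,high,
Table 1,103,182 + Na+ + H+/2,positive,low,analyte mass 182 matches no library species; printed columns may be merged
Table 1,106,210 + H+ + H+/2,positive,high,
Table 1,120,192 + 2H+ + HCOOH/2,positive,high,
Table 1,122,176 + 2NH4+ + CH3OH/2,positive,high,
Table 1,123,210 + 2NH4+/2,positive,high,
Table 1,145,194 + 2NH4+ + CH3COOH/2,positive,high,
Table 1,149,180 + 2NH4+ + HCOOH + 2H2O/2,positive,high,
Table 1,149,194 + 2NH4+ + CH3OH + 2H2O/2,positive,high,
Table 1,152,180 + 2Na+ + CH3COOH + H2O/2,positive,high,
Table 1,152,194 + 2Na+ + HCOOH + H2O/2,positive,high,
Table 1,153,210 + 2NH4+ + CH3COOH/2,positive,high,
Table 1,153,192 + 2NH4+ + H2O + CH3COOH/2,positive,high,
Table 1,158,210 + 2Na+ + CH3COOH/2,positive,high,
Table 1,158,192 + 2Na+ + H2O + CH3COOH/2,positive,high,
Table 1,161,180 + 2Na+ + CH3COOH + 2H2O/2,positive,high,
Table 1,161,194 + 2Na+ + HCOOH + 2H2O/2,positive,high,
Table 1,163,196 + Na+ + H+ + CH3COOH + HCOOH/2,positive,high,
Table 1,163,210 + Na+ + H+ + 2HCOOH/2,positive,high,
Table 1,166,210 + 2H+ + 2CH3COOH/2,positive,high,
Table 1,166,192 + 2H+ + H2O + 2CH3COOH/2,positive,high,
Table 1,167,196 + 2Na+ + CH3COOH + CH3OH/2,positive,high,
Table 1,167,210 + 2Na+ + HCOOH + CH3OH/2,positive,high,
Table 1,168,180 + 2NH4+ + 2CH3COOH/2,positive,high,
Table 1,168,194 + 2NH4+ + HCOOH + CH3COOH/2,positive,high,
Table 1,170,180 + 2NH4+ + 2HCOOH + CH3OH/2,positive,high,
Table 1,170,194 + 2NH4+ + HCOOH + 2CH3OH/2,positive,high,
Table 1,173,194 + 2Na+ + CH3COOH + HCOOH/2,positive,high,
Table 1,173,180 + 2Na+ + 2CH3COOH/2,positive,high,
Table 1,174,156 + NH4+,positive,high,
Table 1,175,174 + H+,positive,high,
Table 1,178,180 + 174 + 2H+/2,positive,high,
Table 1,179,178 + H+,positive,high,
Table 1,180,180 + 178 + 2H+/2,positive,high,
Table 1,181,180 + H+,positive,high,
Table 1,184,192 + 174 + 2H+/2,positive,high,
Table 1,185,194 + 174 + 2H+/2,positive,high,
Table 1,186,196 + 174 + 2H+/2,positive,high,
Table 1,187,180 + 192 + 2H+/2,positive,high,
Table 1,191,174 + 174 + 2H+ + CH3OH/2,positive,high,
Table 1,193,192 + H+,positive,high,
Table 1,195,194 + H+,positive,high,
Table 1,203,180 + Na+,positive,high,
Table 1,206,192 + 174 + 2Na+/2,positive,high,
Table 1,210,192 + NH4+,positive,high,
Table 1,212,194 + NH4+,positive,high,
Table 1,214,196 + NH4+,positive,high,
Table 1,215,192 + Na+,positive,high,
Table 1,216,180 + NH4+ + H2O,positive,high,
Table 1,217,194 + Na+,positive,high,
Table 1,228,210 + NH4+,positive,high,
Table 1,232,196 + NH4+ + H2O,positive,high,
Table 1,233,210 + Na+,positive,high,
Table 1,254,176 + NH4+ + CH3COOH,positive,high,
Table 1,256,178 + NH4+ + CH3COOH,positive,high,
Table 1,256,192 + NH4+ + HCOOH,positive,high,
Table 1,257,196 + H+ + CH3COOH,positive,high,
Table 1,257,210 + H+ + HCOOH,positive,high,
Table 1,264,210 + NH4+ + 2H2O,positive,high,
Table 1,265,210 + Na+ + CH3OH,positive,high,
Table 1,265,196 + Na+ + HCOOH,positive,high,
Table 1,267,174 + H+ + 2HCOOH,positive,high,
Table 1,272,194 + NH4+ + CH3COOH,positive,high,
Table 1,273,194 + H+ + CH3COOH + H2O,positive,high,
Table 1,274,196 + NH4+ + CH3COOH,positive,high,
Table 1,274,210 + NH4+ + HCOOH,positive,high,
Table 1,294,180 + NH4+ + CH3COOH + 2H2O,positive,high,
Table 1,294,194 + NH4+ + HCOOH + 2H2O,positive,high,
Table 2,102,174 - 2H+ + CH3OH/2,negative,high,
Table 2,106,178 - 2H+ + 2H2O/2,negative,high,
Table 2,109,174 - 2H+ + HCOOH/2,negative,high,
Table 2,113,210 - 2H+ + H2O/2,negative,high,
Table 2,121,176 - 2H+ + CH3OH + 2H2O/2,negative,high,
Table 2,122,178 - 2H+ + CH3OH + 2H2O/2,negative,high,
Table 2,127,210 - 2H+ + HCOOH/2,negative,high,
Table 2,135,194 - 2H+ + HCOOH + CH3OH/2,negative,high,
Table 2,135,180 - 2H+ + 2HCOOH/2,negative,high,
Table 2,137,194 - 2H+ + HCOOH + 2H2O/2,negative,high,
Table 2,137,180 - 2H+ + CH3COOH + 2H2O/2,negative,high,
Table 2,139,174 - 2H+ + HCOOH + CH3COOH/2,negative,high,
Table 2,141,178 - 2H+ + HCOOH + CH3COOH/2,negative,high,
Table 2,141,192 - 2H+ + 2HCOOH/2,negative,high,
Table 2,151,176 - 2H+ + 2H2O + CH3OH + CH3COOH/2,negative,high,
Table 2,151,194 - 2H+ + H2O + CH3OH + CH3COOH/2,negative,high,
Table 2,155,174 - 2H+ + H2O + 2CH3COOH/2,negative,high,
Table 2,155,192 - 2H+ + 2CH3COOH/2,negative,high,
Table 2,162,194 - 2H+ + 3H2O + HCOOH + CH3OH/2,negative,high,
Table 2,162,180 - 2H+ + 3H2O + 2HCOOH/2,negative,high,
Table 2,168,210 - 2H+ + 2H2O + CH3OH + CH3COOH/2,negative,high,
Table 2,168,196 - 2H+ + 2H2O + HCOOH + CH3COOH/2,negative,high,
Table 2,171,194 - 2H+ + 4H2O + CH3OH + HCOOH/2,negative,high,
Table 2,171,180 - 2H+ + 4H2O + 2HCOOH/2,negative,high,
Table 2,173,174 - H+,negative,high,
Table 2,175,176 - H+,negative,high,
Table 2,187,180 + 196 - 2H+/2,negative,high,
Table 2,189,180 + 178 - 3H+ + Na+/2,negative,high,
Table 2,193,194 - H+,negative,high,
Table 2,195,196 - H+,negative,high,
Table 2,196,180 - H+ + NH3,negative,high,
Table 2,197,180 - H+ + H2O,negative,high,
Table 2,200,210 + 192 - 2H+/2,negative,high,
Table 2,204,196 + 196 - 2H+ + H2O/2,negative,high,
Table 2,204,180 + 194 - 2H+ + 2H2O/2,negative,high,
Table 2,206,180 + 180 - 2H+ + 3H2O/2,negative,high,
Table 2,218,210 + 210 - 2H+ + H2O/2,negative,high,
Table 2,224,176 - H+ + NH3 + CH3OH,negative,high,
Table 2,227,210 - H+ + H2O,negative,high,
Table 2,230,196 - H+ + NH3 + H2O,negative,high,
Table 2,233,174 - H+ + CH3COOH,negative,high,
Table 2,236,174 - H+ + NH3 + HCOOH,negative,high,
Table 2,240,192 - H+ + NH3 + CH3OH,negative,high,
Table 2,240,178 - H+ + NH3 + HCOOH,negative,high,
Table 2,243,194 - H+ + CH3OH + H2O,negative,high,
Table 2,243,180 - H+ + HCOOH + H2O,negative,high,
Table 2,249,196 - H+ + 3H2O,negative,high,
Table 2,252,176 - H+ + NH3 + CH3COOH,negative,high,
Table 2,259,192 - 2H+ + Na+ + HCOOH,negative,high,
Table 2,259,178 - 2H+ + Na+ + CH3COOH,negative,high,
Table 2,261,194 - 2H+ + Na+ + HCOOH,negative,high,
Table 2,261,180 - 2H+ + Na+ + CH3COOH,negative,high,
Table 2,265,194 - H+ + 4H2O,negative,high,
Table 2,269,210 - H+ + CH3COOH,negative,high,
Table 2,272,210 - H+ + NH3 + HCOOH,negative,high,
Table 2,272,196 - H+ + NH3 + CH3COOH,negative,high,
Table 2,277,196 - 2H+ + Na+ + CH3COOH,negative,high,
Table 2,277,210 - 2H+ + Na+ + HCOOH,negative,high,
Table 2,278,180 - H+ + NH3 + 2H2O + HCOOH,negative,high,
Table 2,278,194 - H+ + NH3 + 2H2O + CH3OH,negative,high,printed as CH3O; arithmetic requires CH3OH
Table 2,281,210 - H+ + 4H2O,negative,high,
Table 2,285,194 - H+ + CH3OH + CH3COOH,negative,high,
Table 2,285,180 - H+ + HCOOH + CH3COOH,negative,high,
Table 2,289,194 - H+ + 2H2O + CH3COOH,negative,high,
Table 2,289,180 - H+ + H2O + CH3OH + CH3COOH,negative,high,
Table 2,291,196 - H+ + 2H2O + CH3COOH,negative,high,
Table 2,291,210 - H+ + 2H2O + HCOOH,negative,high,
Table 2,292,180 - H+ + NH3 + 2H2O + CH3COOH,negative,high,
Table 2,292,194 - H+ + NH3 + 2H2O + HCOOH,negative,high,
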