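# Default causal structure for the aboveground fresh-weight path model.
# Exogenous drivers: light intensity (LI), genotype score (G), interaction (LIxG).
# Intermediates: free proline (FPC), plant height (PH), leaf thickness (LT),
# chlorophyll index (SPAD), stem diameter (SD). Terminal response: AFW.
LI -> FPC
LI -> PH
LI -> LT
LI -> SPAD
LI -> SD
G -> FPC
G -> PH
G -> LT
G -> SPAD
G -> SD
LIxG -> FPC
LIxG -> PH
LIxG -> LT
LIxG -> SPAD
LIxG -> SD
PH -> AFW
LT -> AFW
SPAD -> AFW
SD -> AFW
FPC -> AFW
LI -> AFW
G -> AFW
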