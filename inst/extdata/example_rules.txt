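# Rule set table for a radiomics cohort: one directive per line.
# Explicit actions are hard constraints; preferential actions are
# suggestions the preprocessing algorithms may overrule.

# the clinician insists these prominent features enter every model
feature exp-keep name=TLG_g_Total,Coarseness

# texture features of this family are suspected to be informative
feature pref-keep pattern=NGTDM_*

# drop a feature known to be acquisition-dependent at this site
feature exp-remove name=GLCM_f001

# very old patients are suspected protocol deviations, prefer to drop them
sample pref-remove where=age>80
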