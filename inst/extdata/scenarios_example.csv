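# Example confounder scenarios for an ultra-processed-food / weight-gain
# analysis. Association strengths are drawn from published meta-analyses and
# large surveys of each confounder; baseline risks (p0) are the values that
# reproduce the commonly quoted risk-ratio conversions:
#   depression:      exposure OR 1.44 with p0 = 0.08  -> RR ~ 1.39
#                    outcome  OR 1.58 with p0 = 0.117 -> RR ~ 1.48
#   food_insecurity: exposure RR 1.60 (reported directly)
#                    outcome  OR 1.53 with p0 = 0.146 -> RR ~ 1.42
#   overeating:      outcome  r 0.28 -> OR 2.88 -> RR ~ 1.49 at the
#                    conservative default p0 = 0.5; the exposure side is not
#                    well quantified, so it is set to the closed-form
#                    threshold (~1.60) at which the scenario produces total
#                    confounding of an observed RR of 1.14
name,exposure_assoc_type,exposure_assoc_value,exposure_p0,outcome_assoc_type,outcome_assoc_value,outcome_p0
depression,or,1.44,0.08,or,1.58,0.117
food_insecurity,rr,1.60,,or,1.53,0.146
overeating,rr,1.60,,r,0.28,0.5
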