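# Shared vocabulary. Order matters: severities and checkpoints are ordinal.

SEVERITY_LEVELS <- c("none", "mild", "moderate", "severe")
EVENT_CATEGORIES <- c("seizure", "hyperactivity")
LATENCY_CATEGORIES <- c("sternal_posture", "unstimulated_movement",
                        "movement_without_ataxia", "grooming_eating_nesting")
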