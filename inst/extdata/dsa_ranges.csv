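parameter,lower,upper,comparison
transitions.perioperative_death,0.001,0.9,ALL
transitions.local_recurrence_2y.WW,0.16,0.999,ALL
transitions.local_recurrence_5y.WW,0.2,0.999,ALL
transitions.local_recurrence_2y.TME,0.01,0.999,ALL
transitions.local_recurrence_5y.TME,0.005,0.999,ALL
transitions.salvage_given_local.WW,0.1,0.95,ALL
transitions.salvage_given_local.TME,0.01,0.8,ALL
transitions.distant_recurrence_5y.WW,0.05,0.999,ALL
transitions.distant_recurrence_5y.TME,0.05,0.999,ALL
transitions.concurrent_distant_given_local,0.01,0.9,ALL
transitions.concurrent_local_given_distant,0.01,0.9,ALL
transitions.distant_after_local_3y,0.01,0.999,ALL
transitions.mortality_local_salvaged_5y,0.1,0.999,ALL
transitions.mortality_local_unsalvaged_5y,0.1,0.999,ALL
transitions.mortality_distant_5y,0.1,0.999,ALL
transitions.mortality_local_and_distant_5y,0.1,0.999,ALL
natural_mortality_monthly,0.001,0.9,ALL
utilities.initial_ww,0.05,0.95,ALL
utilities.initial_postop,0.05,0.95,ALL
utilities.salvage_tme_disutility_state,0.05,0.95,ALL
utilities.longterm_apr,0.1,0.9,APR
utilities.longterm_lar_with_ostomy,0.05,0.95,LAR
utilities.longterm_lar_without_ostomy,0.05,0.95,LAR
utilities.local_recurrence,0.01,0.95,ALL
utilities.distant_recurrence,0.01,0.95,ALL
utilities.local_and_distant,0.0048,0.96,ALL
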