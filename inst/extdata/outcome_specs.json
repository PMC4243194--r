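{
  "outcomes": [
    {
      "outcome_id": "accept_violence",
      "eligible": "all",
      "rule": "any_yes",
      "direction": "decrease",
      "items": ["av_disobey", "av_answer_back", "av_disrespect",
                "av_suspect_unfaithful", "av_unfaithful", "av_gossip",
                "av_neglect_children", "av_housework", "av_refuse_sex",
                "av_accuse_infidelity", "av_tell_secrets", "av_angry"]
    },
    {
      "outcome_id": "accept_refuse_sex",
      "eligible": "all",
      "rule": "any_yes",
      "direction": "increase",
      "items": ["rs_refuse"]
    },
    {
      "outcome_id": "physical_ipv",
      "eligible": "women_partnered",
      "rule": "any_yes",
      "direction": "decrease",
      "items": ["pv_slap", "pv_push", "pv_fist", "pv_kick", "pv_choke",
                "pv_weapon", "pv_panga"]
    },
    {
      "outcome_id": "sexual_ipv",
      "eligible": "women_partnered",
      "rule": "any_yes",
      "direction": "decrease",
      "items": ["sv_forced", "sv_afraid"]
    },
    {
      "outcome_id": "community_response",
      "eligible": "women_with_ipv",
      "rule": "helped_and_any_response",
      "direction": "increase",
      "items": ["cr_helped", "cr_gathered", "cr_knocked", "cr_separated",
                "cr_informed", "cr_asked", "cr_told"]
    },
    {
      "outcome_id": "concurrency",
      "eligible": "men_nonpoly_regular",
      "rule": "any_yes",
      "direction": "decrease",
      "items": ["cc_other_partner"]
    }
  ]
}
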