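# Published index-locus (3'-UTR U635C) carrier rows of the two screening cohorts:
# patient carrier IDs as printed, control carriers as a printed count (control IDs unpublished).
cohort	n_sle	n_control	n_control_carriers	sle_carrier_ids
1	101	163	0	S2,S7,S8,S16,S17,S29,S30,F10-4,F13-1,F14-1,F14-2,F15-1,F15-2,F18-1,F18-2,F19-3,F53-3
2	80	87	14	B14,B15,B16,B21,B22,B23,B24,B26,B29,B30,B31,B32,B37,B38,B39,B40,B41,B42,B47,B48,B53,B54,B55,B58,B61,B63,B64,B65,B67,B69,B70,B71,B73,B75,B76,B77,B79
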