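study_id	ancestries
ANC_01	EUR
ANC_02	EUR
ANC_03	EUR
ANC_04	EUR
ANC_05	EUR
ANC_06	EUR
ANC_07	EUR
ANC_08	EUR
ANC_09	EUR
ANC_10	EUR
ANC_11	EUR
ANC_12	EUR
ANC_13	EUR
ANC_14	EUR
ANC_15	EUR
ANC_16	EUR
ANC_17	EUR
ANC_18	EUR
ANC_19	EUR
ANC_20	EUR
ANC_21	EUR
ANC_22	EUR
ANC_23	EUR
ANC_24	EUR
ANC_25	EUR
ANC_26	EUR
ANC_27	EUR
ANC_28	EUR
ANC_29	EUR
ANC_30	EUR
ANC_31	EUR
ANC_32	EAS;EUR
ANC_33	EAS;EUR
ANC_34	EAS;EUR
ANC_35	EAS;EUR
ANC_36	EAS;EUR
ANC_37	AFR;EUR
ANC_38	AFR;EAS;EUR
ANC_39	AFR;EAS;EUR
ANC_40	AFR;EAS;EUR
ANC_41	AFR;EAS
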