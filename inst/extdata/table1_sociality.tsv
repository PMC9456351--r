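species	sociality	NACC1	SP110	EPM2A
Cheetah	1	0	1	1
Weddell_seal	1	0	1	1
Tiger	1	0	1	1
Duck-billed_platypus	1	1	0	1
Lesser_Egyptian_jerboa	1	1	0	1
Opossum	1	1	0	1
Galago	1	1	0	1
Orangutan	1	1	0	1
Tasmanian_devil	1	1	0	1
West_Indian_manatee	1	1	0	1
Hedgehog	1	1	1	0
Pika	1	1	1	0
Deer_mouse	1	1	1	0
solitary_extra_01	1	1	1	1
solitary_extra_02	1	1	1	1
solitary_extra_03	1	1	1	1
solitary_extra_04	1	1	1	1
solitary_extra_05	1	1	1	1
solitary_extra_06	1	1	1	1
solitary_extra_07	1	1	1	1
solitary_extra_08	1	1	1	1
solitary_extra_09	1	1	1	1
solitary_extra_10	1	1	1	1
solitary_extra_11	1	1	1	1
solitary_extra_12	1	1	1	1
solitary_extra_13	1	1	1	1
solitary_extra_14	1	1	1	1
Elephant_shrew	0	1	0	1
Bottlenosed_dolphin	0	1	0	1
social_extra_01	0	1	1	1
social_extra_02	0	1	1	1
social_extra_03	0	1	1	1
social_extra_04	0	1	1	1
social_extra_05	0	1	1	1
social_extra_06	0	1	1	1
social_extra_07	0	1	1	1
social_extra_08	0	1	1	1
social_extra_09	0	1	1	1
social_extra_10	0	1	1	1
social_extra_11	0	1	1	1
social_extra_12	0	1	1	1
social_extra_13	0	1	1	1
social_extra_14	0	1	1	1
social_extra_15	0	1	1	1
social_extra_16	0	1	1	1
social_extra_17	0	1	1	1
social_extra_18	0	1	1	1
social_extra_19	0	1	1	1
social_extra_20	0	1	1	1
social_extra_21	0	1	1	1
social_extra_22	0	1	1	1
social_extra_23	0	1	1	1
social_extra_24	0	1	1	1
social_extra_25	0	1	1	1
social_extra_26	0	1	1	1
social_extra_27	0	1	1	1
social_extra_28	0	1	1	1
social_extra_29	0	1	1	1
social_extra_30	0	1	1	1
social_extra_31	0	1	1	1
social_extra_32	0	1	1	1
social_extra_33	0	1	1	1
social_extra_34	0	1	1	1
social_extra_35	0	1	1	1
social_extra_36	0	1	1	1
social_extra_37	0	1	1	1
social_extra_38	0	1	1	1
social_extra_39	0	1	1	1
social_extra_40	0	1	1	1
social_extra_41	0	1	1	1
social_extra_42	0	1	1	1
social_extra_43	0	1	1	1
social_extra_44	0	1	1	1
social_extra_45	0	1	1	1
social_extra_46	0	1	1	1
social_extra_47	0	1	1	1
social_extra_48	0	1	1	1
social_extra_49	0	1	1	1
social_extra_50	0	1	1	1
social_extra_51	0	1	1	1
social_extra_52	0	1	1	1
social_extra_53	0	1	1	1
social_extra_54	0	1	1	1
social_extra_55	0	1	1	1
social_extra_56	0	1	1	1
social_extra_57	0	1	1	1
social_extra_58	0	1	1	1
social_extra_59	0	1	1	1
social_extra_60	0	1	1	1
social_extra_61	0	1	1	1
social_extra_62	0	1	1	1
social_extra_63	0	1	1	1
social_extra_64	0	1	1	1
social_extra_65	0	1	1	1
social_extra_66	0	1	1	1
social_extra_67	0	1	1	1
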