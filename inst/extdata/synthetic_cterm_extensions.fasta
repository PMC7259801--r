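>human_p54_extension synthetic reconstruction of the canonical long C-terminal extension (39 aa)
SQTAGKLEFHRAMELDDQRSKNPVAYEWSTFVNHQPLID
>jnk1b_lg_extension synthetic reconstruction of the divergent fish paralog extension (9 divergent substitutions + 1 inserted threonine)
SGTAGDLEPHRWMEDDDQTRSKWPVAYFWSTPVNHQGLID
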