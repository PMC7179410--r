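index,name,printed_mz,computed_mz_2dp,flagged
1,(+)Syringaresinol,491.14,491.19,TRUE
2,Lutonarin,609.14,609.15,FALSE
3,Trifloroside,781.22,781.22,FALSE
4,4-b-d-glu-trifloroside,943.27,943.27,FALSE
5,4''-O-b-d-glucopyranosy1-6'-O-(4-O-b-d-glucopyranosylcaffeoyl)linearroside,1007.30,1007.30,FALSE
6,Macrophylloside A,875.22,875.23,FALSE
7,Scabraside,843.24,843.24,FALSE
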