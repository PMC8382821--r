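>seed_at synthetic aminotransferase-like seed (carries one exact consensus-motif instantiation at 145-174)
ETVFHQQMKRPTCKKTKDRMFLHHFCDRMFPFPHNRREDSVDRFFSFTDIKTQRGNHGMD
RQLKSWPLCECPQYTLDKAFTRPIHRRKLTCHMATCAVMWEVFVYVMRLRLPHTNQWVIW
WIHMCQQGENCFQLFAFDVRWVFESGNSFRVYHFPNTYMKYCILCVPYPYCYRCLVLRDW
WIDIQFRLASQERGAGDYAAIAFQSPPQDDCHWKVSYDNDSWGRLAHPYTTSGLLRKNDP
LENAQTSGEQSNPRQRARWCMIQADYWNEHAMKFFEDFVLHQANMPPLHGWEYQTMFDAQ
SNVIPPINITWNQRAREYHDGLAGKVIEGVVQCGLNFPLHYDLVEDIFVLQFGWDNGIEV
PDNCICIPAMEKWRQSWPGDTSDCDNQTNWIHSESNLARW
>seed_dh synthetic dehydrogenase-like seed
YVLNGHHLAWVAWISASVHGATTAQHPLSYGRDHLYACVVAGVDRAEKPPRAYLTTTSMG
RKARIVKFTHEDTVMCRLILPNCGTTHLLNHYSPGLMNTTAVMCYGHQEDVSFGRTLENR
IVWEGKMTHEQASYVMDVEIDAYNDCVLTLYISLKPEELFKLEDNHWCDYQMHCQYHATF
AGDQTMEMWTMEQVSRQEYYLAAWCDAPPKGEDGKDDHHGYHRERWELLDGVSHGRDNFD
AGFWVPSYKHPEAPYYHAANGFYSTNDRCEWSMISDKENWIAITQQHCPAPGCTFFQAYD
SDCKVHTVCIHHPENMWIGMVMTKSWAYYMWLWGVPMQICMGGFCVNNSLELRRKYKVCT
VYLSGIIFIDDGMQKLLHHYLGPLAADVGVIAKQYQHWSM
>seed_ph_inositol synthetic inositol-phosphatase-like seed
INPNQIESAEQNDRKPEMIICDIFSNFARQWAHFGISQDQDAADTLTWYMGAKSMMHMEH
LLDYWNSMGEGRACEYSRTKDDHTCRPHAGVHSIQKMPMAMAVTGYQPMAPGEKFVRRDK
NDHEDNDWEQNCAFNMWGLMDQWADITTLQHMARGVESHQGYNRADIFACSHRNELGAWF
IGAICVMDKEIPRFDHLGTHAEFCMHWGSFAAQPDWQQMHEVNWYQWIQCDESSMDCRWA
DYSEVLSFEWFTYCHTECVRSMNTHYIMIRDCYVKYCNHNMDQGWQDDVQCSNEQMDGYV
CHENGNCADIPGARKTYEIDVDVQMGAKFTAYDVGMRQFYEPLSKQVMMWSAQSQELGAP
FHCKFNEAENRFGHRLLFDIGMWFKINSEKYTVHPCCLCP
>seed_ph_had synthetic HAD-hydrolase-like seed
QQSSWCKVFYHFRFSPYMIWCNMMVFGEIYTFASTMEFLNRRQPFFIRKWANGPAFWQEP
AHRDDCLQVETKWDDIIQYPTTHPCTFTVWEKLHGKHDIYWYTELSDKNWFPAVQYHWAD
QEMLRRSGWFYPATETMLSRQTLIRVKNTQEAGFAHYFIDMLLVPRLPCDFPYFHCWKYQ
IDPEFMPPRNLIYPMQLQGWAGCVHQRPSCRNRQKAFGHLHEQFIMDGCKDTNKKAMEIS
LMMLYYYCIERCGMDRDWHYCNGAMTYYFPNDDRFLKVKSSYHLFGCTSANVCCPFQKPK
VEQLPHQYKIRMLCAAIFSNTDTDYVALPDHSEHSDGVYVCDDVWRRLSIISCFPTSGYN
NQGATRCSKQKLDFLSQDGWYVLKFVMDQYQVVPCEISYT
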