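>SYN0001
EAYDNKYLVSVKRCVCGYQKLCALAWQAQIIKTCSRFHNRATPVFDERGCEGMFSCKNCPFKQTPGDDIRCGYYSINSQQGGKYASSNCQVTMNNCKQVKDEPSKYAGSYQQYWPVETQEDMTSVFYH
>SYN0002
KHDITESAGEDVPMKHPVDAFDWNRGSMAYPDCNQLWEAHDKEPGSEFHTLDEMAVNDMIRNNNDEYCLGDMRYKWIMEVRDLKRRLIHRWVKDVDEQIFKWICYADEPYFTGPVE
>SYN0003
KMWSAIVEESDEEWVCSNYYMTNGSTSFHIPWWKSTSKHDRFQEKIVKLLQLAAYDMIRQWYPNYWLDTYKGDKFEHPEA
>SYN0004
FFDVVHLQKKYKDSRDCLCPYIGNEKIYYTTAPGETAADEWEKFLMAYYTDCIGTMNDITKCSPDILISKQQVRRLRCVDYDFTGLLQPDFHKSELCMTMGWEH
>SYN0005
NYMNVFNLILCGEKRLDRWWDCLAMAMEPGSTLMLYPRIDYRCDELLLRFVYTNHRDEDKVNILCVCRPIAVQEWPTCHTDEQMPEVLT
>SYN0006
NCNKCPLQDRIFGKRFLHIEHEMSDKVKMATMAHFTWIYYVKRHAEIQGYPKQQWQWYPSKEYGCGGPRMDEQHGKITGMVHMVINTFAANEPCACPSFDEKRQSIEDACYKRPH
>SYN0007
KQEDRTKTVWLDWDEVPRQGQMPDEDMPYCVDHVYDPCHFPDLPNHFSGPYGVIFNFGAFAYGKDWAPPSPFNMYMLDYILKRPFIPTWSDEYEADV
>SYN0008
TCDTHIQVDHSDIWGPFANVQWRTEHHKHWSWSSAFTAHDGIAALRWVSQVFKHEPRCVFRTAKNKEVRHLSVDHEGCDNDLDECMTYTAFILRRFTTRERFPQFNDEVNGHVLRYPMMDAFNEGFREHCDECSQLI
>SYN0009
HTLRANFPRKANCQVRFAYETYQSMDCKFHGFWDLILIGKMCCRVTTTYTLPTYEFTEQQWRVGENRQAQHVTDECMATRVHIEPVTQEWYMFLDENCHRYQNRASIKIWLCDDEMLPCRSSPDPNMR
>SYN0010
GLIEKPTNHYNWTRDTGEVAKDCLFDTIIAIRLKTTIHRSSLFEMYHMRLDEYYDEFRHVFYLWIWDECLPENPDSQFNTLIMQQNQKIDENMELGVVVAGVFHGQEQCQQMLESSMHREIQFLTI
>SYN0011
QMPWFTETHYLNFRTTGGDEVVEHVECLPNYHSFVTHFQQWQDWVMDCISAMRYMSVCLNSEKCCTRCIYHKNHYFQCVRSCNQSELRETQPCCFDMALYIMV
>SYN0012
TQMLIRCLVKVKSSITVAWFPGMSCYYDEIRGVAMYFPKAFMSGLMMNKDWLEILRDHMRMSQKNMSAMYNYYNDEYSTNIANCCL
>SYN0013
RTFHFPFYNCWFFPPDETEGWQHRYMGNSFWQAFGDEEVVIYSWIAECCGRCKNAEEQIMTCKRRYYHADNWGPEYHHIGEWSYDEISESEQTPNHCIMDNAFYEQIWGIHSCLL
>SYN0014
KDAVMFKLFRITMDDFWLNDYPVLYADDSKKEMFHYPDNYCKVSPEFVEWDEDVPKYYPHSPDEDRFWTTFESWLIQPEYFQMILRCISKCAIWNPDEDAIVMD
>SYN0015
WKASYKTGMRMYICGCIDSSQWEHWAYRYSENISITIHHGHHFFHNKYPNSIVRGINYAHIQTGDEWESNFFDEWQVYCMPGDELVHPLFCKEAMGTRPRSRFQYKWSSHLSVLHT
>SYN0016
LTAQKMPPLEHAVQHNNKKHCWSPPEFVYTEDEGGFERTPNFKNNRFPPYPDETMCEWVGDDAQYPRMDHRTCQKFTDTDNMLSQWDEKPALCRYPSMKQAIMAACNYSAHNFVCKHWTWEEEDI
>SYN0017
CYYNGKKANNGRHYRHCIPKRPNCTITTTQYQIDQPLMTNDEHYQLLHGLNTRMLIDERYEFLKLEAACIQVPNNLYKIGMYVDENMEMISVNFGHFTM
>SYN0018
WSSVLSKDQCRKPLDLVDHGDEEAYSWMQCKKETNTVRLYTCAEEMTPAHEWWCCFSYQVGDDDEQPDFQAVWFMRTEPSIFKKLEFTMLARDSPMVMFRASCMF
>SYN0019
IWKNDELNWHTITTCYVNGPLPGPMDESETYPFSDHVPLSMMIMGIYSHQEAGLWNCFNVLKCPSVLYILYKFPKWTNDPGTNTQWDCYEMEDQDDVLARGANLWMKPLHECMYAKAGFQSHYVSIFVT
>SYN0020
GIRYVRKRIGNDHGIRATKNEICQHHGRDEEARCCYVHPWYDSKYPPFRHDRLDEEWFMPCYRTQDSGACQTWFLMISSLVFGNWDFAICPAPSPHIQGMLAKAQDEKTPHGLFYKQYEISQNYER
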