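taxon_id	name	species	genus	family	order	class	is_excluded	regions
x001	Macaca mulatta	Macaca mulatta	Macaca	Cercopithecidae	Primates	Mammalia	FALSE	
x002	Macaca fascicularis	Macaca fascicularis	Macaca	Cercopithecidae	Primates	Mammalia	FALSE	
x003	Homo sapiens	Homo sapiens	Homo	Hominidae	Primates	Mammalia	TRUE	
x004	Viverra zibetha	Viverra zibetha	Viverra	Viverridae	Carnivora	Mammalia	FALSE	
x005	Paradoxurus hermaphroditus	Paradoxurus hermaphroditus	Paradoxurus	Viverridae	Carnivora	Mammalia	FALSE	
x006	Herpestes javanicus	Herpestes javanicus	Herpestes	Herpestidae	Carnivora	Mammalia	FALSE	
x007	Civettictis civetta	Civettictis civetta	Civettictis	Viverridae	Carnivora	Mammalia	FALSE	
x008	Muntiacus muntjak	Muntiacus muntjak	Muntiacus	Cervidae	Artiodactyla	Mammalia	FALSE	
x009	Rusa unicolor	Rusa unicolor	Rusa	Cervidae	Artiodactyla	Mammalia	FALSE	
x010	Tragulus kanchil	Tragulus kanchil	Tragulus	Tragulidae	Artiodactyla	Mammalia	FALSE	
x011	Bos taurus	Bos taurus	Bos	Bovidae	Artiodactyla	Mammalia	TRUE	
x012	Bubalus bubalis	Bubalus bubalis	Bubalus	Bovidae	Artiodactyla	Mammalia	TRUE	
x013	Sus scrofa	Sus scrofa	Sus	Suidae	Artiodactyla	Mammalia	TRUE	
x014	Niviventer excelsior	Niviventer excelsior	Niviventer	Muridae	Rodentia	Mammalia	FALSE	
x015	Rattus rattus	Rattus rattus	Rattus	Muridae	Rodentia	Mammalia	TRUE	
x016	Menetes berdmorei	Menetes berdmorei	Menetes	Sciuridae	Rodentia	Mammalia	FALSE	
x017	Tupaia belangeri	Tupaia belangeri	Tupaia	Tupaiidae	Scandentia	Mammalia	FALSE	
x018	Hipposideros bicolor	Hipposideros bicolor	Hipposideros	Hipposideridae	Chiroptera	Mammalia	FALSE	
x019	Gallus gallus	Gallus gallus	Gallus	Phasianidae	Galliformes	Aves	TRUE	
x020	Lophura nycthemera	Lophura nycthemera	Lophura	Phasianidae	Galliformes	Aves	FALSE	
x021	Fejervarya multistriata	Fejervarya multistriata	Fejervarya	Dicroglossidae	Anura	Amphibia	FALSE	
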